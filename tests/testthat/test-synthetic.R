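test_that("recipes are validated and reproducible", {
  expect_error(generator_recipe(), "seed")
  r <- generator_recipe(42, noise_sigma = 0.02)
  p <- hn_process(5, 1e-3, 0.8, 0.5)
  g1 <- gen_hn_spectrum(r, p)
  g2 <- gen_hn_spectrum(r, p)
  expect_identical(g1$data, g2$data)
  # a different seed gives different noise
  g3 <- gen_hn_spectrum(generator_recipe(43, noise_sigma = 0.02), p)
  expect_false(identical(g1$data$eps_imag, g3$data$eps_imag))
  # generators do not disturb the caller's RNG stream
  set.seed(1); before <- rnorm(1)
  set.seed(1); invisible(gen_hn_spectrum(r, p)); after <- rnorm(1)
  expect_identical(before, after)
})

test_that("noiseless spectra equal the forward model bit for bit", {
  p <- hn_process(5, 1e-3, 0.8, 0.5)
  g <- gen_hn_spectrum(generator_recipe(1), p, eps_inf = 3, sigma_dc = 1e-9)
  eps <- hn_model(p, eps_inf = 3, sigma_dc = 1e-9, frequency = g$data$frequency)
  expect_identical(g$data$eps_real, Re(eps))
  expect_identical(g$data$eps_imag, -Im(eps))
  # truth is always carried alongside the data
  expect_equal(g$truth$tau_alpha[[1L]], tau_alpha(p))
})

test_that("replicate noise averages back to the noiseless curve", {
  p <- hn_process(5, 1e-3, 0.8, 0.5)
  clean <- gen_hn_spectrum(generator_recipe(1), p)$data$eps_imag
  reps <- vapply(1:100, function(s) {
    gen_hn_spectrum(generator_recipe(s, noise_sigma = 0.02), p)$data$eps_imag
  }, numeric(length(clean)))
  m <- rowMeans(reps)
  se <- 0.02 * clean / sqrt(100)
  # pointwise 3-standard-error bound (allowing the expected ~1% exceedances)
  expect_gte(mean(abs(m - clean) <= 3 * se), 0.95)
})

test_that("thermogram generator conserves peak areas analytically", {
  peaks <- list(list(center = 130, area = 58.5, width = 3,
                     direction = "exothermic"))
  g <- gen_thermogram(generator_recipe(1), tg_onset = 58, delta_cp = 0.45,
                      width = 4, peaks = peaks, t_range = c(30, 170),
                      dT = 0.05)
  tgm <- g$data
  idx <- tgm$temperature >= 115 & tgm$temperature <= 145
  x <- tgm$temperature[idx]
  # by 115 degC the Cp step (onset 58) is fully developed: baseline 1.6 + 0.45
  y <- tgm$signal[idx] - (1.6 + 0.45)
  area <- abs(sum(diff(x) * (y[-1] + y[-length(y)]) / 2))
  expect_equal(area, 58.5, tolerance = 1e-6)
  # a peak overlapping the glass transition is flagged
  expect_warning(
    gen_thermogram(generator_recipe(1), tg_onset = 58, delta_cp = 0.45,
                   width = 4, t_range = c(30, 170),
                   peaks = list(list(center = 66, area = 10, width = 3,
                                     direction = "exothermic"))),
    "overlaps")
})

test_that("mixture-series generator plants a recoverable straight line", {
  # planting a straight delta_cp line requires the rigid fraction to grow
  # super-linearly with load (the drug fraction shrinks at the same time)
  gen <- gen_mixture_series(generator_recipe(1), pure_delta_cp = 0.45,
                            pure_cc_enthalpy = 60,
                            fraction_model = fix_linear_dcp_model(0.839),
                            ms_fractions = seq(0, 0.8, by = 0.1))
  ext <- extrapolate_full_rigid_load(gen$data)
  expect_equal(ext$ms_fraction_full_rigid, 0.839, tolerance = 1e-9)
  expect_equal(ext$r_squared, 1, tolerance = 1e-9)
  # noisy recovery of the fraction triple within 3 percentage points;
  # an additive sigma of 0.002 J/(g K) on a 0.45 J/(g K) pure step keeps
  # the per-point fraction noise below ~1.1 points at these drug loads
  genn <- gen_mixture_series(
    generator_recipe(6, noise_sigma = 0.002, noise_model = "additive"),
    pure_delta_cp = 0.45, pure_cc_enthalpy = 60,
    fraction_model = function(f) c(30 * f, 50 * (1 - f)),
    ms_fractions = seq(0, 0.6, by = 0.15))
  for (i in seq_along(genn$data)) {
    p <- decompose_fractions(genn$data[[i]], 0.45, 60)
    expect_lt(abs(p$rigid - genn$truth$fractions[[i]][["rigid"]]), 3)
    expect_lt(abs(p$free - genn$truth$fractions[[i]][["free"]]), 3)
  }
})

test_that("avrami trace generator validates and reproduces", {
  expect_error(gen_avrami_trace(generator_recipe(1), k = 1e-7, plateau = 1.2),
               "plateau")
  expect_error(gen_avrami_trace(generator_recipe(1), k = 1e-7, eps0 = 3,
                                eps_inf = 8), "eps0")
  g1 <- gen_avrami_trace(generator_recipe(3, noise_sigma = 0.01,
                                          noise_model = "additive"),
                         k = 1.59e-7, d = 907, n = 1.8)
  g2 <- gen_avrami_trace(generator_recipe(3, noise_sigma = 0.01,
                                          noise_model = "additive"),
                         k = 1.59e-7, d = 907, n = 1.8)
  expect_identical(g1$data, g2$data)
})
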