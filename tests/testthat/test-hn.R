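test_that("HN forward model matches frozen arbitrary-precision values", {
  # 40-digit mpmath evaluation of eps_inf + deps/(1+(i w tau)^a)^b at
  # deps = 5, tau = 1e-3 s, a = 0.8, b = 0.5, eps_inf = 3, f = 100 Hz
  p <- hn_process(delta_eps = 5, tau_hn = 1e-3, a = 0.8, b = 0.5)
  v <- hn_model(p, eps_inf = 3, sigma_dc = 0, frequency = 100)
  expect_equal(Re(v), 7.12781077865213, tolerance = 1e-10)
  expect_equal(Im(v), -1.04430401509901, tolerance = 1e-10)
  # same with sigma_dc = 1e-9 S/m (eps_0 = 8.8541878128e-12 F/m)
  v2 <- hn_model(p, eps_inf = 3, sigma_dc = 1e-9, frequency = 100)
  expect_equal(Im(v2), -1.22405505094423, tolerance = 1e-10)
})

test_that("Debye and conductivity limits of the forward model", {
  # Debye half-height identity: at w tau = 1 the loss is deps / 2
  deb <- hn_process(delta_eps = 4, tau_hn = 1e-2, a = 1, b = 1)
  f_half <- 1 / (2 * pi * 1e-2)
  expect_equal(-Im(hn_model(deb, 1, 0, f_half)), 2, tolerance = 1e-12)
  # conductivity-only loss falls with log-log slope -1
  f <- 10^seq(-2, 2, 0.5)
  loss <- sigma_loss <- 1e-9 / (poreglass::pg_constants$eps_0 * 2 * pi * f)
  tiny <- hn_process(1e-9, 1e-12, 1, 1)
  model_loss <- -Im(hn_model(tiny, 1, 1e-9, f))
  slopes <- diff(log10(model_loss)) / diff(log10(f))
  expect_equal(slopes, rep(-1, length(slopes)), tolerance = 1e-6)
  expect_error(hn_model(deb, 1, 1e-9, c(0, 1)), "positive")
})

test_that("tau_alpha equals the reciprocal angular loss-peak frequency", {
  expect_equal(tau_alpha(hn_process(1, 1e-3, 1, 1)), 1e-3)
  # numeric peak oracle on two shape cases
  p1 <- hn_process(5, 1e-3, 0.8, 0.5)
  expect_equal(tau_alpha(p1), numeric_loss_peak_tau(p1), tolerance = 0.005)
  p2 <- hn_process(2, 1, 0.6, 0.9)
  expect_equal(tau_alpha(p2), numeric_loss_peak_tau(p2), tolerance = 0.005)
})

test_that("tau_alpha matches the numeric peak for 100 random shapes", {
  set.seed(404)
  for (i in 1:100) {
    p <- hn_process(delta_eps = 1, tau_hn = 10^runif(1, -8, 0),
                    a = runif(1, 0.3, 1), b = runif(1, 0.3, 1))
    expect_equal(tau_alpha(p), numeric_loss_peak_tau(p), tolerance = 0.01)
  }
})

test_that("fit_hn recovers noiseless parameters to self-consistency", {
  truth <- hn_process(5, 1e-3, 0.8, 0.5)
  g <- gen_hn_spectrum(generator_recipe(1), truth, eps_inf = 3, sigma_dc = 0)
  fit <- fit_hn(g$data, seed = 2)
  p <- fit$processes[[1L]]
  expect_equal(p$delta_eps, 5, tolerance = 1e-3)
  expect_equal(p$tau_hn, 1e-3, tolerance = 1e-3)
  expect_equal(p$a, 0.8, tolerance = 1e-3)
  expect_equal(p$b, 0.5, tolerance = 1e-3)
})

test_that("fit_hn recovers a single process with conductivity at 2 % noise", {
  truth <- hn_process(5, 1e-3, 0.8, 0.5)
  g <- gen_hn_spectrum(generator_recipe(21, noise_sigma = 0.02), truth,
                       eps_inf = 3, sigma_dc = 1e-9)
  fit <- fit_hn(g$data, seed = 5)
  p <- fit$processes[[1L]]
  expect_equal(p$delta_eps, 5, tolerance = 0.05)
  expect_equal(p$tau_hn, 1e-3, tolerance = 0.05)
  expect_lt(abs(p$a - 0.8), 0.05)
  expect_lt(abs(p$b - 0.5), 0.05)
  expect_equal(fit$sigma_dc, 1e-9, tolerance = 0.2)
})

test_that("fit_hn degrades gracefully at doubled noise", {
  truth <- hn_process(5, 1e-3, 0.8, 0.5)
  g <- gen_hn_spectrum(generator_recipe(22, noise_sigma = 0.04), truth,
                       eps_inf = 3, sigma_dc = 0)
  p <- fit_hn(g$data, seed = 5)$processes[[1L]]
  expect_equal(p$delta_eps, 5, tolerance = 0.10)
  expect_equal(p$tau_hn, 1e-3, tolerance = 0.10)
  expect_lt(abs(p$a - 0.8), 0.10)
  expect_lt(abs(p$b - 0.5), 0.10)
})

test_that("two-process deconvolution separates a 1000x tau ratio", {
  slow <- hn_process(6, 1e-1, 0.85, 0.6)
  fast <- hn_process(2, 1e-4, 0.85, 0.6)
  g <- gen_hn_spectrum(generator_recipe(11, noise_sigma = 0.02),
                       list(slow, fast), eps_inf = 3, sigma_dc = 0)
  fit <- fit_hn(g$data, n_processes = 2, seed = 5)
  # slower process is always first (label-switching broken by construction)
  expect_gt(fit$processes[[1L]]$tau_hn, fit$processes[[2L]]$tau_hn)
  expect_equal(fit$processes[[1L]]$tau_hn, 1e-1, tolerance = 0.10)
  expect_equal(fit$processes[[2L]]$tau_hn, 1e-4, tolerance = 0.10)
})

test_that("Kramers-Kronig sanity: loss-fitted deps equals the eps' step", {
  truth <- hn_process(5, 1e-3, 0.8, 0.5)
  g <- gen_hn_spectrum(generator_recipe(1), truth, eps_inf = 3, sigma_dc = 0,
                       f_min = 1e-4, f_max = 1e7)
  fit <- fit_hn(g$data, seed = 2)
  eps_step <- max(g$data$eps_real) - min(g$data$eps_real)
  expect_equal(fit$processes[[1L]]$delta_eps, eps_step, tolerance = 0.02)
})

test_that("normalize_loss scales the peak to one", {
  truth <- hn_process(5, 1e-3, 0.8, 0.5)
  g <- gen_hn_spectrum(generator_recipe(1), truth, eps_inf = 3, sigma_dc = 0)
  nl <- normalize_loss(g$data)
  expect_identical(max(nl$loss), 1)
  expect_false(nl$boundary_peak)
  # idempotent: re-normalizing a normalized spectrum changes nothing
  sp2 <- dielectric_spectrum(nl$frequency, g$data$eps_real, nl$loss,
                             g$data$temperature)
  expect_equal(normalize_loss(sp2)$loss, nl$loss)
  # peak at the grid boundary is flagged
  low <- hn_process(5, 1e3, 1, 1)   # peak far below the grid
  g2 <- gen_hn_spectrum(generator_recipe(1), low, eps_inf = 3, sigma_dc = 0)
  expect_warning(nl2 <- normalize_loss(g2$data), "boundary")
  expect_true(nl2$boundary_peak)
})

test_that("conductivity subtraction restores the relaxation peak", {
  truth <- hn_process(5, 1e-3, 0.8, 0.5)
  sigma <- 5e-9
  g <- gen_hn_spectrum(generator_recipe(9), truth, eps_inf = 3,
                       sigma_dc = sigma)
  fit <- fit_hn(g$data, seed = 3)
  nl <- normalize_loss(g$data, sigma_dc = fit$sigma_dc)
  f_peak_truth <- 1 / (2 * pi * tau_alpha(truth))
  # within one grid step (8 points per decade)
  expect_lt(abs(log10(nl$peak_frequency) - log10(f_peak_truth)), 1 / 8 + 1e-9)
})
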