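## Synthetic-data generators. Every generator returns a (data, truth,
## recipe) triplet, is bit-reproducible under its recipe seed, and reduces
## exactly to the corresponding forward model in the noiseless limit, so
## each analysis stage can be tested against known ground truth.

#' Recipe controlling a synthetic-data generator
#'
#' @param seed Mandatory integer seed.
#' @param noise_sigma Noise level; interpretation depends on
#'   `noise_model`.
#' @param noise_model `"multiplicative"` (`x * (1 + sigma Z)`, the default
#'   for spectra, whose instrument noise scales with signal) or
#'   `"additive"` (`x + sigma Z`, the default choice for conversion
#'   traces).
#' @return An object of class `generator_recipe`.
#' @export
generator_recipe <- function(seed, noise_sigma = 0,
                             noise_model = c("multiplicative", "additive")) {
  noise_model <- match.arg(noise_model)
  if (missing(seed) || !is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("a single integer seed is mandatory", call. = FALSE)
  }
  stopifnot(noise_sigma >= 0)
  structure(list(seed = as.integer(seed), noise_sigma = noise_sigma,
                 noise_model = noise_model),
            class = "generator_recipe")
}

with_recipe_seed <- function(recipe, expr) {
  old_seed <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  set.seed(recipe$seed)
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, .GlobalEnv)
          else rm(".Random.seed", envir = .GlobalEnv))
  force(expr)
}

apply_noise <- function(recipe, x) {
  if (recipe$noise_sigma == 0) return(x)
  z <- stats::rnorm(length(x))
  switch(recipe$noise_model,
         multiplicative = x * (1 + recipe$noise_sigma * z),
         additive = x + recipe$noise_sigma * z)
}

#' Generate a synthetic dielectric spectrum with known truth
#'
#' Forward-evaluates [hn_model()] on a log-spaced grid (the default
#' 1e-2 to 1e7 Hz sweep of a broadband spectrometer) and applies recipe
#' noise to both components. Noiseless output equals the forward model
#' exactly.
#'
#' @param recipe A [generator_recipe()].
#' @param processes A [hn_process()] or list of them.
#' @param eps_inf High-frequency permittivity.
#' @param sigma_dc dc conductivity, S/m.
#' @param temperature Sample temperature, K.
#' @param f_min,f_max,points_per_decade Frequency grid.
#' @return A list (class `synthetic_data`) with `data`
#'   (a [dielectric_spectrum()]), `truth`, `recipe`.
#' @export
gen_hn_spectrum <- function(recipe, processes, eps_inf = 3, sigma_dc = 0,
                            temperature = 347.15, f_min = 1e-2, f_max = 1e7,
                            points_per_decade = 8) {
  stopifnot(inherits(recipe, "generator_recipe"))
  if (inherits(processes, "hn_process")) processes <- list(processes)
  n_dec <- log10(f_max) - log10(f_min)
  f <- 10^seq(log10(f_min), log10(f_max), length.out = round(n_dec * points_per_decade) + 1)
  eps <- hn_model(processes, eps_inf = eps_inf, sigma_dc = sigma_dc, frequency = f)
  re <- Re(eps); im <- -Im(eps)
  with_recipe_seed(recipe, {
    re <- apply_noise(recipe, re)
    im <- apply_noise(recipe, im)
  })
  structure(list(
    data = dielectric_spectrum(f, re, im, temperature),
    truth = list(processes = processes, eps_inf = eps_inf, sigma_dc = sigma_dc,
                 tau_alpha = vapply(processes, tau_alpha, numeric(1))),
    recipe = recipe), class = "synthetic_data")
}

#' Generate a synthetic VFT relaxation-time series with known truth
#'
#' @param recipe A [generator_recipe()]; noise is applied additively on
#'   `log10 tau` (so `noise_sigma = 0.03` means 3 % scatter in decades).
#' @param tau0,D,T0 VFT parameters (see [vft_tau()]).
#' @param temperatures Temperatures, K, all above `T0`.
#' @return A list (class `synthetic_data`) with `data` (a data frame of
#'   `temperature_K`, `tau_s`), `truth`, `recipe`.
#' @export
gen_vft_series <- function(recipe, tau0, D, T0, temperatures) {
  stopifnot(inherits(recipe, "generator_recipe"))
  tau <- vft_tau(temperatures, tau0, D, T0)
  if (recipe$noise_sigma > 0) {
    with_recipe_seed(recipe, {
      tau <- 10^(log10(tau) + recipe$noise_sigma * stats::rnorm(length(tau)))
    })
  }
  structure(list(
    data = data.frame(temperature_K = temperatures, tau_s = tau),
    truth = list(tau0 = tau0, D = D, T0 = T0),
    recipe = recipe), class = "synthetic_data")
}

#' Generate a synthetic DSC heating trace with known truth
#'
#' A sigmoidal (logistic) heat-capacity step at the glass transition plus
#' Gaussian exo-/endothermic peaks on a linear baseline. The logistic
#' scale is `width / 4`, so the tangent construction of
#' [detect_glass_transition()] recovers `tg_onset` and `width` exactly in
#' the noiseless continuum limit; Gaussian peak areas equal the requested
#' enthalpies analytically. Noise is additive in signal units.
#'
#' @param recipe A [generator_recipe()] (use `noise_model = "additive"`;
#'   `noise_sigma` is in J/(g K)).
#' @param tg_onset Onset glass-transition temperature, degC.
#' @param delta_cp Step height, J/(g K).
#' @param width Onset-to-end transition width, K.
#' @param peaks List of peaks, each `list(center, area, width, direction)`
#'   with center degC, area J/g, Gaussian sigma K, direction
#'   `"exothermic"` / `"endothermic"`.
#' @param baseline Length-2 `c(intercept, slope)` of the linear baseline,
#'   J/(g K) and J/(g K)/degC.
#' @param t_range Length-2 temperature range, degC.
#' @param dT Temperature step, K.
#' @param heating_rate K/min (metadata only; the signal is generated on a
#'   Cp basis).
#' @return A list (class `synthetic_data`) with `data` (a
#'   [thermogram()]), `truth` (including `tg_mid`, `tg_end`), `recipe`.
#' @export
gen_thermogram <- function(recipe, tg_onset = 58, delta_cp = 0.45, width = 4,
                           peaks = list(), baseline = c(1.6, 0),
                           t_range = c(20, 180), dT = 0.1, heating_rate = 10) {
  stopifnot(inherits(recipe, "generator_recipe"), width > 0, delta_cp >= 0)
  temp <- seq(t_range[[1]], t_range[[2]], by = dT)
  tg_mid <- tg_onset + width / 2
  w_scale <- width / 4
  sig <- baseline[[1]] + baseline[[2]] * temp +
    delta_cp / (1 + exp(-(temp - tg_mid) / w_scale))
  overlap <- FALSE
  for (p in peaks) {
    stopifnot(p$width > 0, p$area >= 0)
    s <- if (identical(p$direction, "exothermic")) -1 else 1
    sig <- sig + s * p$area / (p$width * sqrt(2 * pi)) *
      exp(-(temp - p$center)^2 / (2 * p$width^2))
    if (abs(p$center - tg_mid) < 3 * p$width + 2 * width) overlap <- TRUE
  }
  if (overlap) {
    warning("a peak overlaps the glass-transition window", call. = FALSE)
  }
  with_recipe_seed(recipe, {
    if (recipe$noise_sigma > 0) sig <- sig + recipe$noise_sigma * stats::rnorm(length(sig))
  })
  structure(list(
    data = thermogram(temp, sig, heating_rate = heating_rate,
                      signal_kind = "cp", mass_mg = 5),
    truth = list(tg_onset = tg_onset, tg_mid = tg_mid,
                 tg_end = tg_onset + width, delta_cp = delta_cp,
                 width = width, peaks = peaks, baseline = baseline,
                 overlap = overlap),
    recipe = recipe), class = "synthetic_data")
}

#' Generate a synthetic isothermal crystallization trace with known truth
#'
#' Avrami-Erofeev conversion sampled on a regular time grid (default the
#' 600 s cadence of an isothermal dielectric run). When `eps0`/`eps_inf`
#' are given a BDS-kind permittivity trace is produced whose
#' [epsilon_n()] inverse reproduces the conversion exactly in the
#' noiseless case; otherwise a DSC-kind crystallinity trace. Noise is
#' additive (in conversion or permittivity units, per the recipe).
#'
#' @param recipe A [generator_recipe()].
#' @param k,d,n,plateau Avrami parameters (see [avrami_model()]).
#' @param eps0,eps_inf Optional endpoints for a permittivity-kind trace.
#' @param times Time grid, s; default `seq(0, 36000, by = 600)`.
#' @param temperature Annealing temperature, K.
#' @return A list (class `synthetic_data`) with `data` (a
#'   [crystallization_trace()]), `truth`, `recipe`.
#' @export
gen_avrami_trace <- function(recipe, k, d = 0, n = 2, plateau = 1,
                             eps0 = NULL, eps_inf = NULL,
                             times = seq(0, 36000, by = 600),
                             temperature = 368.15) {
  stopifnot(inherits(recipe, "generator_recipe"))
  if (plateau > 1) stop("plateau must not exceed 1", call. = FALSE)
  x <- avrami_model(times, k, d, n, plateau)
  bds <- !is.null(eps0)
  if (bds) {
    if (is.null(eps_inf) || eps0 <= eps_inf) {
      stop("permittivity traces need eps0 > eps_inf", call. = FALSE)
    }
    obs <- eps0 - x * (eps0 - eps_inf)
  } else {
    obs <- x
  }
  with_recipe_seed(recipe, obs <- apply_noise(recipe, obs))
  if (!bds) obs <- pmin(pmax(obs, 0), 1)
  structure(list(
    data = crystallization_trace(times, obs, kind = if (bds) "bds" else "dsc",
                                 temperature = temperature),
    truth = list(k = k, d = d, n = n, plateau = plateau, eps0 = eps0,
                 eps_inf = eps_inf, conversion = x),
    recipe = recipe), class = "synthetic_data")
}

#' Generate a series of mixture observations with known fraction truth
#'
#' `fraction_model` maps a silica mass fraction to the true
#' `c(rigid, free)` percentages; observables are generated by inverting
#' the fraction formulas (`delta_cp = w * pure_delta_cp * (1 - rigid/100)`,
#' `cc = w * pure_cc_enthalpy * free/100`), so
#' [decompose_fractions()] recovers the planted triple exactly in the
#' noiseless case. Additive recipe noise is applied to `delta_cp` in
#' J/(g K) and to the enthalpy scaled by `pure_cc_enthalpy /
#' pure_delta_cp`, keeping the two observables comparably perturbed.
#'
#' @param recipe A [generator_recipe()].
#' @param pure_delta_cp Pure-drug step, J/(g K).
#' @param pure_cc_enthalpy Pure-drug cold-crystallization enthalpy, J/g.
#' @param fraction_model `function(ms_fraction) -> c(rigid, free)` in
#'   percent.
#' @param ms_fractions Silica mass fractions to generate.
#' @return A list (class `synthetic_data`) with `data` (list of
#'   [mixture_observation()]), `truth` (per-point rigid/free/intermediate),
#'   `recipe`.
#' @export
gen_mixture_series <- function(recipe, pure_delta_cp, pure_cc_enthalpy,
                               fraction_model,
                               ms_fractions = seq(0, 0.8, by = 0.1)) {
  stopifnot(inherits(recipe, "generator_recipe"), is.function(fraction_model))
  truth <- lapply(ms_fractions, function(f) {
    rf <- fraction_model(f)
    if (any(rf < 0) || sum(rf) > 100) {
      stop("fraction_model must return c(rigid, free) percentages summing to <= 100",
           call. = FALSE)
    }
    c(rigid = rf[[1]], free = rf[[2]], intermediate = 100 - rf[[1]] - rf[[2]])
  })
  w <- 1 - ms_fractions
  dcp <- w * pure_delta_cp * (1 - vapply(truth, `[[`, numeric(1), "rigid") / 100)
  cc <- w * pure_cc_enthalpy * vapply(truth, `[[`, numeric(1), "free") / 100
  with_recipe_seed(recipe, {
    if (recipe$noise_sigma > 0) {
      dcp <- pmax(apply_noise(recipe, dcp), 0)
      cc_recipe <- recipe
      cc_recipe$noise_sigma <- recipe$noise_sigma *
        if (recipe$noise_model == "additive") pure_cc_enthalpy / pure_delta_cp else 1
      cc <- pmax(apply_noise(cc_recipe, cc), 0)
    }
  })
  obs <- Map(mixture_observation, ms_fractions, dcp, cc)
  structure(list(data = obs,
                 truth = list(fractions = truth,
                              pure_delta_cp = pure_delta_cp,
                              pure_cc_enthalpy = pure_cc_enthalpy,
                              ms_fractions = ms_fractions),
                 recipe = recipe), class = "synthetic_data")
}
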