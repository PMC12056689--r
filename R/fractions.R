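## Three-fraction decomposition of a drug glass mixed with mesoporous
## silica. The heat-capacity step at Tg counts only the mobile glass, so
## the rigid (surface-immobilised) fraction is the invisible remainder;
## the free (bulk-like) fraction is counted by its cold-crystallization
## enthalpy; the intermediate fraction - mobile but unable to crystallize
## on heating - is the complement.

#' One calorimetric observation of a drug/silica mixture
#'
#' @param ms_mass_fraction Silica mass fraction in `[0, 1)`.
#' @param delta_cp Heat-capacity step at Tg, J/(g K), per gram of mixture.
#' @param cc_enthalpy Cold-crystallization enthalpy, J/g of mixture
#'   (0 when no cold crystallization is seen).
#' @return An object of class `mixture_observation`.
#' @export
mixture_observation <- function(ms_mass_fraction, delta_cp, cc_enthalpy = 0) {
  if (ms_mass_fraction < 0 || ms_mass_fraction >= 1) {
    stop("ms_mass_fraction must lie in [0, 1)", call. = FALSE)
  }
  if (delta_cp < 0 || cc_enthalpy < 0) {
    stop("observables must be non-negative", call. = FALSE)
  }
  structure(list(ms_mass_fraction = ms_mass_fraction, delta_cp = delta_cp,
                 cc_enthalpy = cc_enthalpy),
            class = "mixture_observation")
}

#' Rigid (calorimetrically invisible) fraction of the drug glass
#'
#' With drug mass fraction `w = 1 - ms_mass_fraction`, a fully mobile
#' glass would show a step `w * pure_delta_cp`; the shortfall is the rigid
#' fraction: `rigid = 100 * (1 - delta_cp / (w * pure_delta_cp))`, clipped
#' to `[0, 100]`.
#'
#' @param obs A [mixture_observation()].
#' @param pure_delta_cp Heat-capacity step of the pure drug glass, J/(g K).
#' @return Percent of the drug mass, in `[0, 100]`.
#' @export
rigid_fraction <- function(obs, pure_delta_cp) {
  stopifnot(inherits(obs, "mixture_observation"))
  if (pure_delta_cp <= 0) stop("pure_delta_cp must be positive", call. = FALSE)
  w <- 1 - obs$ms_mass_fraction
  if (w <= 0) stop("drug mass fraction is zero", call. = FALSE)
  min(max(100 * (1 - obs$delta_cp / (w * pure_delta_cp)), 0), 100)
}

#' Free (bulk-like) fraction of the drug glass
#'
#' Counted by the cold-crystallization enthalpy relative to the pure
#' glass: `free = 100 * cc_enthalpy / (w * pure_cc_enthalpy)`, clipped to
#' `[0, 100]`.
#'
#' @param obs A [mixture_observation()].
#' @param pure_cc_enthalpy Cold-crystallization enthalpy of the pure drug
#'   glass, J/g.
#' @return Percent of the drug mass, in `[0, 100]`.
#' @export
free_fraction <- function(obs, pure_cc_enthalpy) {
  stopifnot(inherits(obs, "mixture_observation"))
  if (pure_cc_enthalpy <= 0) stop("pure_cc_enthalpy must be positive", call. = FALSE)
  w <- 1 - obs$ms_mass_fraction
  if (w <= 0) stop("drug mass fraction is zero", call. = FALSE)
  min(max(100 * obs$cc_enthalpy / (w * pure_cc_enthalpy), 0), 100)
}

#' Decompose a mixture observation into rigid / intermediate / free
#'
#' The raw triple always sums to exactly 100 by construction
#' (`intermediate = 100 - rigid - free` before clipping); clipping to
#' `[0, 100]` absorbs measurement noise, and the clipped triple is
#' re-normalized to sum to 100 only when clipping pushed the sum above it.
#' Both the clipped and the raw triples are returned.
#'
#' @inheritParams rigid_fraction
#' @inheritParams free_fraction
#' @return An object of class `fraction_profile` with elements `rigid`,
#'   `intermediate`, `free` (percent, clipped) and `raw` (unclipped
#'   diagnostics).
#' @export
decompose_fractions <- function(obs, pure_delta_cp, pure_cc_enthalpy) {
  stopifnot(inherits(obs, "mixture_observation"))
  if (pure_delta_cp <= 0) stop("pure_delta_cp must be positive", call. = FALSE)
  if (pure_cc_enthalpy <= 0) stop("pure_cc_enthalpy must be positive", call. = FALSE)
  w <- 1 - obs$ms_mass_fraction
  if (w <= 0) stop("drug mass fraction is zero", call. = FALSE)
  rigid_raw <- 100 * (1 - obs$delta_cp / (w * pure_delta_cp))
  free_raw <- 100 * obs$cc_enthalpy / (w * pure_cc_enthalpy)
  inter_raw <- 100 - rigid_raw - free_raw
  clip <- function(v) min(max(v, 0), 100)
  triple <- c(rigid = clip(rigid_raw), intermediate = clip(inter_raw),
              free = clip(free_raw))
  if (sum(triple) > 100) triple <- 100 * triple / sum(triple)
  structure(list(rigid = triple[["rigid"]],
                 intermediate = triple[["intermediate"]],
                 free = triple[["free"]],
                 raw = c(rigid = rigid_raw, intermediate = inter_raw,
                         free = free_raw)),
            class = "fraction_profile")
}

#' @export
print.fraction_profile <- function(x, ...) {
  cat(sprintf("<fraction_profile> rigid %.1f%% | intermediate %.1f%% | free %.1f%%\n",
              x$rigid, x$intermediate, x$free))
  invisible(x)
}

#' Extrapolate the silica load at which the glass transition vanishes
#'
#' Ordinary least squares of the per-gram-of-mixture heat-capacity step
#' against the silica mass fraction; the root of the fitted line (where
#' the step extrapolates to zero) is the load at which all drug has become
#' rigid. The step must decrease with silica load, so a non-negative slope
#' is an error. Unweighted OLS is used deliberately: replicate scatter in
#' such series is heteroscedastic, but no weights are available in
#' general.
#'
#' @param observations A list of [mixture_observation()] objects, at least
#'   3, spanning at least 0.2 in silica mass fraction.
#' @return An object of class `rigid_extrapolation`:
#'   `ms_fraction_full_rigid` (the root), `slope`, `intercept`,
#'   `r_squared`.
#' @export
extrapolate_full_rigid_load <- function(observations) {
  stopifnot(is.list(observations),
            all(vapply(observations, inherits, logical(1), "mixture_observation")))
  if (length(observations) < 3L) {
    stop("need at least 3 observations to extrapolate", call. = FALSE)
  }
  x <- vapply(observations, `[[`, numeric(1), "ms_mass_fraction")
  y <- vapply(observations, `[[`, numeric(1), "delta_cp")
  if (diff(range(x)) < 0.2) {
    stop("observations must span at least 0.2 in ms_mass_fraction", call. = FALSE)
  }
  fit <- stats::lm(y ~ x)
  co <- stats::coef(fit)
  if (!is.finite(co[[2]]) || co[[2]] >= 0) {
    stop("no extrapolation: delta_cp does not decrease with silica load", call. = FALSE)
  }
  root <- -co[[1]] / co[[2]]
  sst <- sum((y - mean(y))^2)
  r2 <- if (sst > 0) 1 - sum(stats::residuals(fit)^2) / sst else 1
  structure(list(ms_fraction_full_rigid = root, slope = co[[2]],
                 intercept = co[[1]], r_squared = r2),
            class = "rigid_extrapolation")
}

#' @export
print.rigid_extrapolation <- function(x, ...) {
  cat(sprintf("<rigid_extrapolation> full-rigid load %.1f%% MS (slope %.3g, r2 %.4f)\n",
              100 * x$ms_fraction_full_rigid, x$slope, x$r_squared))
  invisible(x)
}
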