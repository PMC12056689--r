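## Vogel-Fulcher-Tammann temperature dependence of the alpha relaxation
## time: tau(T) = tau_0 * exp(D * T_0 / (T - T_0)). Fitted on log10 tau,
## where measurement noise is approximately homoscedastic.

vft_log10_tau <- function(temperature, log10_tau0, D, T0) {
  log10_tau0 + D * T0 / ((temperature - T0) * log(10))
}

#' Evaluate the VFT equation
#'
#' @param temperature Temperatures, K (all above `T0`).
#' @param tau0 Vibrational time scale, s.
#' @param D Strength (fragility) parameter, dimensionless.
#' @param T0 Vogel temperature, K (analogous to the Kauzmann temperature).
#' @return Relaxation times, s.
#' @export
vft_tau <- function(temperature, tau0, D, T0) {
  stopifnot(tau0 > 0, D > 0, T0 >= 0)
  if (any(temperature <= T0)) stop("temperatures must exceed T0", call. = FALSE)
  tau0 * exp(D * T0 / (temperature - T0))
}

#' Fit the VFT equation to relaxation times
#'
#' Least squares on `log10 tau` over `(log10 tau0, D, T0)`. Initialization
#' scans a grid of candidate `T0` values (each giving a linear
#' least-squares problem in the remaining two parameters) and the best
#' candidate seeds a Levenberg-Marquardt refinement with `T0` constrained
#' below the lowest fitted temperature. Three exact points are recovered
#' exactly (interpolation); Arrhenius-like data drive `T0` toward 0, where
#' the product `D*T0` plays the role of an activation temperature `E_a/k_B`.
#'
#' @param temperature Temperatures, K (>= 4 points for an overdetermined
#'   fit; exactly 3 points interpolate).
#' @param tau Relaxation times, s, same length.
#' @return An object of class `vft_fit`: `tau0`, `D`, `T0`, `residual`
#'   (RMS on log10 tau).
#' @examples
#' T <- seq(330, 370, length.out = 12)
#' fit_vft(T, vft_tau(T, 1e-14, 8, 270))
#' @export
fit_vft <- function(temperature, tau) {
  stopifnot(length(temperature) == length(tau), all(tau > 0),
            all(is.finite(temperature)), all(is.finite(tau)))
  if (length(temperature) < 3L) {
    stop("VFT fit needs at least 3 (T, tau) points", call. = FALSE)
  }
  y <- log10(tau)
  T_min <- min(temperature)

  ## grid-scan initialization: for fixed T0 the model is linear in
  ## (log10 tau0, D*T0)
  t0_grid <- seq(0, 0.98 * T_min, length.out = 60L)
  best <- NULL
  for (t0 in t0_grid) {
    x <- 1 / ((temperature - t0) * log(10))
    co <- stats::coef(stats::lm(y ~ x))
    if (!all(is.finite(co)) || co[[2]] <= 0) next
    sse <- sum((co[[1]] + co[[2]] * x - y)^2)
    if (is.null(best) || sse < best$sse) {
      best <- list(t0 = t0, log10_tau0 = co[[1]], DT0 = co[[2]], sse = sse)
    }
  }
  if (is.null(best)) stop("VFT initialization failed (tau not increasing on cooling?)", call. = FALSE)

  t0_init <- max(best$t0, 1e-3)
  par0 <- c(best$log10_tau0, best$DT0 / t0_init, t0_init)
  fit <- minpack.lm::nls.lm(
    par = par0,
    lower = c(-30, 1e-6, 1e-4),
    upper = c(5, 1e4, T_min - 1e-6),
    fn = function(p) vft_log10_tau(temperature, p[[1]], p[[2]], p[[3]]) - y,
    control = minpack.lm::nls.lm.control(maxiter = 1000, ftol = 1e-15,
                                         ptol = 1e-15))
  p <- fit$par
  res <- sqrt(mean((vft_log10_tau(temperature, p[[1]], p[[2]], p[[3]]) - y)^2))
  structure(list(tau0 = 10^p[[1]], D = p[[2]], T0 = p[[3]], residual = res,
                 n = length(temperature)),
            class = "vft_fit")
}

#' @export
print.vft_fit <- function(x, ...) {
  cat(sprintf("<vft_fit> tau0 %.3g s, D %.3f, T0 %.2f K (n = %d, RMS(log10 tau) %.3g)\n",
              x$tau0, x$D, x$T0, x$n, x$residual))
  invisible(x)
}
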