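## Isothermal crystallization kinetics. Conversion follows the
## Avrami-Erofeev law X(t) = plateau * (1 - exp(-k (t - d)^n)) for t > d
## (0 during the induction period), with k the rate constant (units
## s^-n for dimensional consistency; the widely printed s^-1 convention is
## reported alongside), d the induction time and n the Avrami exponent.

#' Normalized dielectric conversion
#'
#' Converts a static-permittivity reading into a crystallization
#' conversion: `eps_N = (eps0 - eps_t) / (eps0 - eps_inf)`, clipped to
#' `[0, 1]`.
#'
#' @param eps0 Initial static permittivity (fully amorphous).
#' @param eps_inf Long-time limiting permittivity.
#' @param eps_t Permittivity at time t (vectorized).
#' @return Conversion in `[0, 1]`.
#' @export
epsilon_n <- function(eps0, eps_inf, eps_t) {
  if (eps0 <= eps_inf) stop("eps0 must exceed eps_inf", call. = FALSE)
  pmin(pmax((eps0 - eps_t) / (eps0 - eps_inf), 0), 1)
}

#' Convert a BDS permittivity trace to a conversion trace
#'
#' @param trace A [crystallization_trace()] of kind `"bds"`.
#' @param eps0 Initial static permittivity; defaults to the first reading.
#' @param eps_inf Long-time limiting permittivity. Must be supplied or
#'   derivable from a settled tail (see [terminal_conversion()]); it is
#'   never extrapolated silently.
#' @return A [crystallization_trace()] of kind `"dsc"` holding conversions.
#' @export
epsilon_n_trace <- function(trace, eps0 = NULL, eps_inf = NULL) {
  stopifnot(inherits(trace, "crystallization_trace"))
  if (trace$kind != "bds") stop("trace is not a permittivity (bds) trace", call. = FALSE)
  if (is.null(eps0)) eps0 <- trace$observable[[1L]]
  if (is.null(eps_inf)) {
    n <- length(trace$time)
    tail_idx <- seq.int(ceiling(0.8 * n), n)
    tail_obs <- trace$observable[tail_idx]
    slope <- stats::coef(stats::lm(tail_obs ~ trace$time[tail_idx]))[[2]]
    rel_drift <- abs(slope) * diff(range(trace$time[tail_idx])) /
      max(abs(eps0 - mean(tail_obs)), 1e-12)
    if (rel_drift > 0.02) {
      stop("eps_inf not supplied and the trace has no settled tail to estimate it from",
           call. = FALSE)
    }
    eps_inf <- mean(tail_obs)
  }
  crystallization_trace(time = trace$time,
                        observable = epsilon_n(eps0, eps_inf, trace$observable),
                        kind = "dsc", temperature = trace$temperature)
}

#' Avrami-Erofeev conversion model
#'
#' @param time Times, s.
#' @param k Rate constant, s^-n.
#' @param d Induction time, s (>= 0).
#' @param n Avrami exponent, > 0.
#' @param plateau Terminal conversion in (0, 1].
#' @return Conversion values; exactly 0 for `time <= d`.
#' @export
avrami_model <- function(time, k, d, n, plateau = 1) {
  stopifnot(k > 0, d >= 0, n > 0, plateau > 0, plateau <= 1)
  out <- numeric(length(time))
  grow <- time > d
  out[grow] <- plateau * (1 - exp(-k * (time[grow] - d)^n))
  out
}

#' Fit the Avrami-Erofeev model to a conversion trace
#'
#' Nonlinear least squares over `(log10 k, d, n)` (Levenberg-Marquardt
#' with `d >= 0`), started from a linearized double-log Avrami regression
#' and refined from multiple starts jittered in `log k`. By default the
#' uncrystallized remainder is ignored: the terminal plateau is estimated
#' from the settled tail, conversions are rescaled by it, and the model is
#' fitted with unit plateau (the plateau is still reported). Set
#' `free_plateau = TRUE` to fit the plateau as a fourth parameter instead.
#'
#' @param trace A [crystallization_trace()] holding conversions in
#'   `[0, 1]` (apply [epsilon_n_trace()] or [crystallinity_from_dcp()]
#'   first).
#' @param fix_n Optional: hold the Avrami exponent at this value.
#' @param free_plateau Fit the terminal conversion instead of rescaling.
#' @param n_starts Multi-start count in `log10 k`.
#' @return An object of class `avrami_fit`: `k` (s^-n), `k_per_s` (the
#'   same number under the s^-1 printing convention), `d` (s), `n`,
#'   `plateau`, `residual` (RMS of conversion misfit).
#' @export
fit_avrami <- function(trace, fix_n = NULL, free_plateau = FALSE,
                       n_starts = 5L) {
  stopifnot(inherits(trace, "crystallization_trace"))
  t <- trace$time
  x_raw <- trace$observable
  if (max(x_raw) <= min(x_raw) + 1e-12 ||
      stats::coef(stats::lm(x_raw ~ t))[[2]] <= 0) {
    stop("no crystallization: trace is not increasing", call. = FALSE)
  }
  if (min(x_raw) < -0.05 || max(x_raw) > 1.05) {
    stop("trace is not a conversion in [0, 1]; convert it first", call. = FALSE)
  }

  term <- terminal_conversion(trace)
  plateau_est <- min(max(term$value, max(x_raw)), 1)
  x <- if (free_plateau) x_raw else pmin(x_raw / plateau_est, 1)

  ## linearized Avrami initializer on the interior of the sigmoid
  d0 <- if (any(x > 0.01)) max(0, t[[which(x > 0.01)[[1L]]]] - (t[[2]] - t[[1]])) else 0
  mid <- which(x > 0.05 & x < 0.95 & t > d0)
  if (length(mid) >= 3L) {
    lt <- log(t[mid] - d0)
    ly <- log(-log(1 - pmin(x[mid], 0.999)))
    co <- stats::coef(stats::lm(ly ~ lt))
    n0 <- min(max(co[[2]], 0.3), 6)
    logk0 <- co[[1]] / log(10)
  } else {
    n0 <- 2; logk0 <- log10(log(2)) - n0 * log10(max(stats::median(t), 1))
  }
  if (!is.null(fix_n)) n0 <- fix_n

  model_of <- function(p) {
    pl <- if (free_plateau) p[[4]] else 1
    nn <- if (!is.null(fix_n)) fix_n else p[[3]]
    avrami_model(t, 10^p[[1]], p[[2]], nn, pl)
  }
  resid_fun <- function(p) model_of(p) - x

  par0 <- c(logk0, d0, n0)
  lower <- c(-20, 0, 0.2)
  upper <- c(5, max(t), 8)
  if (free_plateau) {
    par0 <- c(par0, plateau_est); lower <- c(lower, 0.05); upper <- c(upper, 1)
  }
  jitters <- seq(-1, 1, length.out = max(1L, n_starts))
  best <- NULL
  for (j in jitters) {
    p <- par0; p[[1]] <- p[[1]] + j
    p <- pmin(pmax(p, lower), upper)
    fit <- tryCatch(
      minpack.lm::nls.lm(par = p, lower = lower, upper = upper, fn = resid_fun,
                         control = minpack.lm::nls.lm.control(maxiter = 500,
                                                              ftol = 1e-14)),
      error = function(e) NULL)
    if (!is.null(fit) && (is.null(best) || fit$deviance < best$deviance)) best <- fit
  }
  if (is.null(best)) stop("Avrami fit failed from all starts", call. = FALSE)
  p <- best$par
  n_hat <- if (!is.null(fix_n)) fix_n else p[[3]]
  plateau_hat <- if (free_plateau) p[[4]] else plateau_est
  structure(list(k = 10^p[[1]], k_per_s = 10^p[[1]], d = p[[2]], n = n_hat,
                 plateau = plateau_hat,
                 residual = sqrt(best$deviance / length(t)),
                 plateaued = term$plateaued,
                 temperature = trace$temperature),
            class = "avrami_fit")
}

#' @export
print.avrami_fit <- function(x, ...) {
  cat(sprintf("<avrami_fit> k %.3g s^-n (printed convention %.3g s^-1), d %.0f s, n %.2f, plateau %.3f, RMS %.3g\n",
              x$k, x$k_per_s, x$d, x$n, x$plateau, x$residual))
  invisible(x)
}

#' Analytic crystallization half-time
#'
#' Time at which the absolute conversion reaches 0.5:
#' `t_1/2 = d + (-ln(1 - 0.5/plateau) / k)^(1/n)` (the familiar
#' `d + (ln 2 / k)^(1/n)` when the plateau is 1). Undefined when the
#' plateau is below 0.5.
#'
#' @param fit An `avrami_fit`, or a named list with `k`, `d`, `n` and
#'   optionally `plateau`.
#' @return `t_1/2` in seconds.
#' @export
t_half <- function(fit) {
  plateau <- if (is.null(fit$plateau)) 1 else fit$plateau
  if (plateau < 0.5) {
    stop("t_1/2 undefined: terminal conversion below 50%", call. = FALSE)
  }
  fit$d + (-log(1 - 0.5 / plateau) / fit$k)^(1 / fit$n)
}

#' Empirical crystallization half-time
#'
#' Linear interpolation of the first crossing of conversion 0.5 in the
#' trace itself.
#'
#' @param trace A [crystallization_trace()] holding conversions.
#' @return `t_1/2` in seconds.
#' @export
t_half_empirical <- function(trace) {
  stopifnot(inherits(trace, "crystallization_trace"))
  x <- trace$observable; t <- trace$time
  above <- which(x >= 0.5)
  if (!length(above) || above[[1L]] == 1L) {
    stop("trace does not cross 50% conversion after its start", call. = FALSE)
  }
  i <- above[[1L]]
  t[[i - 1L]] + (0.5 - x[[i - 1L]]) * (t[[i]] - t[[i - 1L]]) / (x[[i]] - x[[i - 1L]])
}

#' Terminal conversion (plateau) of a crystallization trace
#'
#' Mean of the settled tail (last `tail_fraction` of points). The tail is
#' deemed settled when its linear drift is statistically indistinguishable
#' from zero at `level`, or negligibly small relative to the signal; an
#' unsettled tail returns the tail mean anyway, flagged with
#' `plateaued = FALSE`.
#'
#' @param trace A [crystallization_trace()] holding conversions.
#' @param tail_fraction Fraction of points regarded as the tail.
#' @param level Significance level of the zero-slope test.
#' @return A list with `value`, logical `plateaued`, and `tail_n`.
#' @export
terminal_conversion <- function(trace, tail_fraction = 0.2, level = 0.05) {
  stopifnot(inherits(trace, "crystallization_trace"))
  n <- length(trace$time)
  idx <- seq.int(max(1L, n - ceiling(tail_fraction * n) + 1L), n)
  tt <- trace$time[idx]; xx <- trace$observable[idx]
  value <- mean(xx)
  plateaued <- if (stats::sd(xx) < 1e-12) TRUE else {
    fit <- stats::lm(xx ~ tt)
    slope <- stats::coef(fit)[[2]]
    df <- length(xx) - 2L
    se <- sqrt(sum(stats::residuals(fit)^2) / df / sum((tt - mean(tt))^2))
    p_slope <- if (se > 0) 2 * stats::pt(-abs(slope / se), df) else as.numeric(slope == 0)
    drift <- abs(slope) * diff(range(tt))
    p_slope > level || drift < 0.005
  }
  if (!plateaued) {
    warning("trace tail still drifting: terminal conversion not plateaued",
            call. = FALSE)
  }
  list(value = value, plateaued = plateaued, tail_n = length(idx))
}
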