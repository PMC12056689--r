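## Glass-transition and peak analysis of DSC heating traces. The onset/end
## construction is the standard tangent method: straight baselines are
## fitted before and after the transition, a tangent is drawn at the point
## of maximum slope, and the onset (end) is the intersection of that
## tangent with the pre- (post-) transition baseline. Delta Cp is the
## vertical separation of the extrapolated baselines at the midpoint.

line_at <- function(coefs, x) coefs[[1]] + coefs[[2]] * x

fit_line <- function(x, y) {
  co <- stats::coef(stats::lm(y ~ x))
  c(intercept = co[[1]], slope = co[[2]])
}

#' Locate a glass transition and measure its parameters
#'
#' Tangent-construction analysis of a heating thermogram inside a search
#' window. The signal is converted to an apparent-specific-heat basis,
#' smoothed with a Savitzky-Golay filter (slope tangents on noisy traces
#' are ill-posed without smoothing), and the maximum-slope tangent is
#' intersected with linear baselines fitted to the outer
#' `baseline_fraction` of the window on each side.
#'
#' @param tg A [thermogram()].
#' @param window Numeric length-2: search window in degC, inside the trace.
#' @param smooth_window Savitzky-Golay window length (odd number of
#'   points; default 11).
#' @param baseline_fraction Fraction of the window used for each baseline
#'   fit (default 0.2).
#' @param dcp_threshold Minimum detectable heat-capacity step, J/(g K);
#'   smaller apparent steps raise a "no glass transition" error.
#' @return An object of class `glass_transition`: `tg_onset`, `tg_end`,
#'   `tg_mid` (degC), `delta_cp` (J/(g K)), `width` and `half_width` (K).
#' @export
detect_glass_transition <- function(tg, window, smooth_window = 11L,
                                    baseline_fraction = 0.2,
                                    dcp_threshold = 0.02) {
  stopifnot(inherits(tg, "thermogram"), length(window) == 2L)
  window <- sort(window)
  tg <- thermogram_as_cp(tg)
  if (window[[1]] < min(tg$temperature) || window[[2]] > max(tg$temperature)) {
    stop("search window extends outside the trace", call. = FALSE)
  }
  idx <- which(tg$temperature >= window[[1]] & tg$temperature <= window[[2]])
  if (length(idx) < 25L) stop("search window holds too few samples", call. = FALSE)
  x <- tg$temperature[idx]
  y <- tg$signal[idx]
  n <- length(x)

  sw <- min(smooth_window, if (n %% 2L) n else n - 1L)
  if (sw %% 2L == 0L) sw <- sw - 1L
  ys <- if (sw >= 5L) signal::sgolayfilt(y, p = 2, n = sw) else y

  nb <- max(5L, floor(baseline_fraction * n))
  pre <- fit_line(x[1:nb], ys[1:nb])
  post <- fit_line(x[(n - nb + 1L):n], ys[(n - nb + 1L):n])

  ## central-difference slope of the smoothed trace
  slope <- c(NA, (ys[-(1:2)] - ys[1:(n - 2L)]) / (x[-(1:2)] - x[1:(n - 2L)]), NA)
  interior <- (nb + 1L):(n - nb)
  imax <- interior[which.max(slope[interior])]
  s_max <- slope[[imax]]
  tangent <- c(intercept = ys[[imax]] - s_max * x[[imax]], slope = s_max)

  if (!is.finite(s_max) || s_max <= max(pre[["slope"]], post[["slope"]])) {
    stop("no glass transition found in window (no slope excursion)", call. = FALSE)
  }
  t_onset <- (tangent[["intercept"]] - pre[["intercept"]]) /
    (pre[["slope"]] - tangent[["slope"]])
  t_end <- (tangent[["intercept"]] - post[["intercept"]]) /
    (post[["slope"]] - tangent[["slope"]])
  if (!is.finite(t_onset) || !is.finite(t_end) || t_end <= t_onset) {
    stop("no glass transition found in window (degenerate tangent construction)",
         call. = FALSE)
  }
  t_mid <- (t_onset + t_end) / 2
  delta_cp <- line_at(post, t_mid) - line_at(pre, t_mid)
  if (delta_cp < dcp_threshold) {
    stop(sprintf("no glass transition found: apparent step %.4g J/(g K) below threshold %.4g",
                 delta_cp, dcp_threshold), call. = FALSE)
  }
  structure(list(tg_onset = t_onset, tg_end = t_end, tg_mid = t_mid,
                 delta_cp = delta_cp, width = t_end - t_onset,
                 half_width = (t_end - t_onset) / 2),
            class = "glass_transition")
}

#' @export
print.glass_transition <- function(x, ...) {
  cat(sprintf("<glass_transition> onset %.2f degC (%.2f K), end %.2f degC, dCp %.4f J/(g K), width %.2f K\n",
              x$tg_onset, x$tg_onset + 273.15, x$tg_end, x$delta_cp, x$width))
  invisible(x)
}

#' Integrate a DSC peak against a linear baseline
#'
#' The baseline is the straight line joining the trace at the two window
#' endpoints (each endpoint value averaged over a few samples for noise
#' robustness); the enthalpy is the absolute area between signal and
#' baseline. On an apparent-specific-heat basis the area is already J/g;
#' heat-flow traces are converted using the declared heating rate first.
#'
#' @param tg A [thermogram()].
#' @param window Numeric length-2: integration window, degC.
#' @param direction `"exothermic"` (peak dips below baseline on a Cp basis)
#'   or `"endothermic"` (peak rises above it).
#' @param edge_points Samples averaged at each window endpoint for the
#'   baseline anchors.
#' @return An object of class `peak_integral`: `t_onset`, `t_peak`,
#'   `t_end` (degC), `enthalpy` (J/g, positive magnitude), `direction`.
#' @export
integrate_peak <- function(tg, window, direction = c("exothermic", "endothermic"),
                           edge_points = 3L) {
  direction <- match.arg(direction)
  stopifnot(inherits(tg, "thermogram"), length(window) == 2L)
  window <- sort(window)
  tg <- thermogram_as_cp(tg)
  if (window[[1]] < min(tg$temperature) || window[[2]] > max(tg$temperature)) {
    stop("integration window extends outside the trace", call. = FALSE)
  }
  idx <- which(tg$temperature >= window[[1]] & tg$temperature <= window[[2]])
  if (length(idx) < 2L * edge_points + 3L) {
    stop("integration window holds too few samples", call. = FALSE)
  }
  x <- tg$temperature[idx]
  y <- tg$signal[idx]
  n <- length(x)
  yl <- mean(y[1:edge_points]); yr <- mean(y[(n - edge_points + 1L):n])
  xl <- mean(x[1:edge_points]); xr <- mean(x[(n - edge_points + 1L):n])
  base <- yl + (yr - yl) * (x - xl) / (xr - xl)
  dev <- y - base
  area <- sum(diff(x) * (dev[-1] + dev[-n]) / 2)   # trapezoid, J/g on Cp basis
  ipk <- if (direction == "endothermic") which.max(dev) else which.min(dev)
  structure(list(t_onset = x[[1]], t_peak = x[[ipk]], t_end = x[[n]],
                 enthalpy = abs(area), direction = direction),
            class = "peak_integral")
}

#' @export
print.peak_integral <- function(x, ...) {
  cat(sprintf("<peak_integral> %s, peak %.2f degC, %.2f J/g (window %.1f-%.1f degC)\n",
              x$direction, x$t_peak, x$enthalpy, x$t_onset, x$t_end))
  invisible(x)
}

#' Crystallinity from the residual glass-transition step
#'
#' The heat-capacity step is proportional to the remaining amorphous
#' fraction, so crystallinity is `X = 1 - dCp(t) / dCp(0)`, clipped to
#' `[0, 1]`.
#'
#' @param dcp_t Step height after annealing, J/(g K) (vectorized).
#' @param dcp_0 Step height of the unannealed glass, J/(g K), > 0.
#' @return Crystallinity in `[0, 1]`.
#' @export
crystallinity_from_dcp <- function(dcp_t, dcp_0) {
  if (!is.numeric(dcp_0) || length(dcp_0) != 1L || dcp_0 <= 0) {
    stop("dcp_0 must be a single positive number", call. = FALSE)
  }
  if (any(dcp_t < 0)) stop("dcp_t must be non-negative", call. = FALSE)
  pmin(pmax(1 - dcp_t / dcp_0, 0), 1)
}
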