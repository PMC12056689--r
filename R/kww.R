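## Frequency-domain Kohlrausch-Williams-Watts (stretched-exponential) loss.
## The decay function Phi(t) = exp(-(t/tau)^beta) has the one-sided Fourier
## loss  L(w) = Int_0^inf sin(w t) (-dPhi/dt) dt = w Int_0^inf cos(w t) Phi(t) dt
## (integration by parts). The cosine integral is evaluated by splitting the
## axis at the zeros of cos(w t), Gauss-Legendre quadrature on each half-period
## lobe, and Wynn epsilon-algorithm acceleration of the alternating partial
## sums - accurate to ~1e-10 uniformly in beta and w t in the ranges used here.

## 16-point Gauss-Legendre rule on [-1, 1] via Golub-Welsch, built at load time.
.gl16 <- local({
  n <- 16L
  k <- seq_len(n - 1L)
  off <- k / sqrt(4 * k^2 - 1)
  J <- matrix(0, n, n)
  J[cbind(k, k + 1L)] <- off
  J[cbind(k + 1L, k)] <- off
  ev <- eigen(J, symmetric = TRUE)
  list(x = ev$values, w = 2 * ev$vectors[1L, ]^2)
})

gl_segment <- function(f, a, b) {
  x <- 0.5 * (b - a) * .gl16$x + 0.5 * (a + b)
  0.5 * (b - a) * sum(.gl16$w * f(x))
}

## Wynn epsilon algorithm: extrapolated limit of a sequence of partial sums.
wynn_limit <- function(S) {
  n <- length(S)
  if (n < 3L) return(S[[n]])
  e0 <- rep(0, n + 1L)   # epsilon_{-1}
  e1 <- S                # epsilon_0
  best <- S[[n]]
  repeat {
    m <- length(e1) - 1L
    if (m < 1L) break
    d <- diff(e1)
    if (any(abs(d) < 1e-300)) break
    e2 <- e0[2:(m + 1L)] + 1 / d
    e0 <- e1
    e1 <- e2
    if (m %% 2L == 0L || length(e2) >= 1L) best <- e2[[length(e2)]]
    if (length(e2) < 2L) break
  }
  best
}

## Cosine transform  C(w) = Int_0^inf cos(w t) exp(-t^beta) dt  (tau = 1).
kww_cos_transform_one <- function(w, beta, tail_sigma = 37) {
  t_max <- tail_sigma^(1 / beta)          # exp(-t^beta) < ~1e-16 beyond
  env <- function(t) exp(-t^beta)
  f <- function(t) cos(w * t) * env(t)
  if (w * t_max < pi / 2) {
    ## no zero crossing before the envelope dies: plain adaptive quadrature
    return(stats::integrate(f, 0, t_max, rel.tol = 1e-12,
                            subdivisions = 400L)$value)
  }
  t1 <- pi / (2 * w)                       # first zero of cos(w t)
  head <- stats::integrate(f, 0, t1, rel.tol = 1e-12, subdivisions = 400L)$value
  n_die <- ceiling((t_max - t1) / (pi / w))
  if (n_die <= 400L) {
    segs <- vapply(seq_len(n_die), function(j)
      gl_segment(f, t1 + (j - 1) * pi / w, t1 + j * pi / w), numeric(1))
    return(head + sum(segs))
  }
  n_acc <- 80L
  segs <- vapply(seq_len(n_acc), function(j)
    gl_segment(f, t1 + (j - 1) * pi / w, t1 + j * pi / w), numeric(1))
  head + wynn_limit(cumsum(segs))
}

## Unnormalized KWW loss at reduced frequency wt = w * tau.
kww_loss_reduced <- function(wt, beta) {
  vapply(wt, function(w) {
    if (w <= 0) return(0)
    w * kww_cos_transform_one(w, beta)
  }, numeric(1))
}

## Peak of the reduced KWW loss: location (in w*tau) and height.
kww_peak <- function(beta) {
  if (beta >= 1) return(list(wt = 1, height = 0.5))  # Debye: peak 1/2 at wt = 1
  opt <- stats::optimize(function(lwt) -kww_loss_reduced(10^lwt, beta),
                         interval = c(-3, 3), tol = 1e-8)
  list(wt = 10^opt$minimum, height = -opt$objective)
}

#' Frequency-domain KWW (stretched-exponential) loss, normalized to unit peak
#'
#' Dielectric loss corresponding to the time-domain decay
#' `Phi(t) = exp(-(t/tau)^beta)`, computed as the one-sided Fourier sine
#' transform of `-dPhi/dt` and scaled so the peak value is exactly 1.
#' `beta = 1` reproduces the Debye loss `w tau / (1 + (w tau)^2)` (peak 1/2
#' before normalization); smaller `beta` gives broader, asymmetric peaks.
#'
#' @param beta Stretching exponent in (0, 1].
#' @param tau_kww Characteristic KWW time, s.
#' @param frequency Frequencies, Hz.
#' @return A list with `frequency`, `loss` (peak-normalized),
#'   `peak_frequency` (analytic peak location, Hz) of class `kww_loss`.
#' @examples
#' kl <- kww_loss(0.69, tau_kww = 1e-2, frequency = 10^seq(-2, 4, 0.25))
#' @export
kww_loss <- function(beta, tau_kww, frequency) {
  if (beta <= 0 || beta > 1) stop("beta must lie in (0, 1]", call. = FALSE)
  stopifnot(tau_kww > 0, all(frequency > 0))
  wt <- 2 * pi * frequency * tau_kww
  pk <- kww_peak(beta)
  structure(list(frequency = frequency,
                 loss = kww_loss_reduced(wt, beta) / pk$height,
                 peak_frequency = pk$wt / (2 * pi * tau_kww),
                 beta = beta, tau_kww = tau_kww),
            class = "kww_loss")
}

#' Fit the KWW stretching exponent to a normalized loss peak
#'
#' Fits the peak-normalized frequency-domain KWW loss shape to a measured,
#' normalized loss spectrum on its log-frequency grid, by box-constrained
#' quasi-Newton least squares over `(beta, log10 tau)` with an analytic
#' amplitude. The input must be single-peaked: the maximum may not sit on
#' the grid boundary.
#'
#' @param spectrum A `normalized_loss` from [normalize_loss()], or any list
#'   with numeric `frequency` and `loss` (peak approximately 1).
#' @param beta_init,tau_init Optional starting values; `tau_init` defaults
#'   to the reciprocal angular peak frequency.
#' @return An object of class `kww_fit` with `beta`, `tau_kww`, `residual`
#'   (RMS of the normalized-loss misfit).
#' @export
fit_kww_beta <- function(spectrum, beta_init = 0.6, tau_init = NULL) {
  f <- spectrum$frequency; y <- spectrum$loss
  stopifnot(is.numeric(f), is.numeric(y), length(f) == length(y))
  ipk <- which.max(y)
  if (ipk == 1L || ipk == length(y)) {
    stop("input is not a resolved single peak (maximum on grid boundary)",
         call. = FALSE)
  }
  if (is.null(tau_init)) tau_init <- 1 / (2 * pi * f[[ipk]])

  shape_resid <- function(par) {
    beta <- par[[1]]; tau <- 10^par[[2]]
    shape <- kww_loss_reduced(2 * pi * f * tau, beta)
    amp <- sum(shape * y) / sum(shape^2)   # best linear amplitude
    sum((amp * shape - y)^2)
  }
  opt <- stats::optim(c(beta_init, log10(tau_init)), shape_resid,
                      method = "L-BFGS-B",
                      lower = c(0.05, log10(tau_init) - 4),
                      upper = c(1, log10(tau_init) + 4),
                      control = list(factr = 1e4))
  beta <- opt$par[[1]]; tau <- 10^opt$par[[2]]
  structure(list(beta = beta, tau_kww = tau,
                 residual = sqrt(opt$value / length(y)),
                 convergence = opt$convergence),
            class = "kww_fit")
}

#' @export
print.kww_fit <- function(x, ...) {
  cat(sprintf("<kww_fit> beta %.3f, tau_KWW %.3g s, RMS %.3g\n",
              x$beta, x$tau_kww, x$residual))
  invisible(x)
}
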