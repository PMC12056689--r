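## Havriliak-Negami analysis of broadband dielectric loss spectra.
## Complex permittivity convention: eps*(w) = eps'(w) - i eps''(w) with the
## loss eps'' >= 0; the dc-conductivity term sigma/(eps_0 w) adds to the loss.

#' One Havriliak-Negami relaxation process
#'
#' @param delta_eps Relaxation strength (dielectric increment), > 0.
#' @param tau_hn HN relaxation time, s.
#' @param a Symmetric-broadening shape exponent in (0, 1].
#' @param b Asymmetric-broadening shape exponent in (0, 1]. `a = b = 1`
#'   recovers the Debye process.
#' @return An object of class `hn_process`.
#' @export
hn_process <- function(delta_eps, tau_hn, a = 1, b = 1) {
  stopifnot(is.numeric(delta_eps), delta_eps > 0,
            is.numeric(tau_hn), tau_hn > 0)
  if (a <= 0 || a > 1 || b <= 0 || b > 1) {
    stop("shape exponents a, b must lie in (0, 1]", call. = FALSE)
  }
  structure(list(delta_eps = delta_eps, tau_hn = tau_hn, a = a, b = b),
            class = "hn_process")
}

#' @export
print.hn_process <- function(x, ...) {
  cat(sprintf("<hn_process> deps %.4g, tau_HN %.4g s, a %.3f, b %.3f (tau_alpha %.4g s)\n",
              x$delta_eps, x$tau_hn, x$a, x$b, tau_alpha(x)))
  invisible(x)
}

#' Havriliak-Negami forward model
#'
#' Complex permittivity of a sum of HN processes plus a dc-conductivity
#' loss term,
#' `eps*(w) = eps_inf + sum_j deps_j / (1 + (i w tau_j)^a_j)^b_j - i sigma_dc/(eps_0 w)`
#' with `w = 2 pi f`.
#'
#' @param processes A single [hn_process()] or a list of them (1-2 typical).
#' @param eps_inf High-frequency limit permittivity (>= 1).
#' @param sigma_dc dc conductivity, S/m (>= 0).
#' @param frequency Frequencies, Hz, all > 0 when `sigma_dc > 0`.
#' @return Complex vector `eps' - i eps''`; the loss is `-Im(.)`.
#' @examples
#' p <- hn_process(delta_eps = 5, tau_hn = 1e-3, a = 0.8, b = 0.5)
#' eps <- hn_model(p, eps_inf = 3, sigma_dc = 0, frequency = 10^seq(-2, 7, 0.1))
#' @export
hn_model <- function(processes, eps_inf = 1, sigma_dc = 0, frequency) {
  if (inherits(processes, "hn_process")) processes <- list(processes)
  stopifnot(all(vapply(processes, inherits, logical(1), "hn_process")))
  if (any(frequency < 0) || (sigma_dc > 0 && any(frequency == 0))) {
    stop("frequencies must be positive when a conductivity term is present",
         call. = FALSE)
  }
  omega <- 2 * pi * frequency
  eps <- complex(real = rep(eps_inf, length(omega)), imaginary = 0)
  for (p in processes) {
    eps <- eps + p$delta_eps / (1 + (1i * omega * p$tau_hn)^p$a)^p$b
  }
  if (sigma_dc > 0) {
    eps <- eps - 1i * sigma_dc / (pg_constants$eps_0 * omega)
  }
  eps
}

## Loss part of the HN model on a frequency grid.
hn_loss <- function(processes, sigma_dc, frequency) {
  -Im(hn_model(processes, eps_inf = 1, sigma_dc = sigma_dc,
               frequency = frequency))
}

#' Alpha relaxation time from HN shape parameters
#'
#' The reciprocal angular frequency of the HN loss maximum,
#' `tau_alpha = tau_HN * sin(a pi / (2 + 2 b))^(-1/a) * sin(a b pi / (2 + 2 b))^(1/a)`.
#'
#' @param process An [hn_process()].
#' @return `tau_alpha` in seconds. Equals `tau_hn` in the Debye limit.
#' @export
tau_alpha <- function(process) {
  stopifnot(inherits(process, "hn_process"))
  a <- process$a; b <- process$b
  process$tau_hn * sin(a * pi / (2 + 2 * b))^(-1 / a) *
    sin(a * b * pi / (2 + 2 * b))^(1 / a)
}

## ---- fitting -------------------------------------------------------------

## Pack/unpack fit parameters. theta layout per process: log10 deps, log10 tau,
## a, b; appended log10 sigma when conductivity is fitted. For two processes the
## second tau is parametrised as tau1 * 10^(-dtau), dtau >= 0, so process 1 is
## always the slower one and label switching cannot occur.
hn_theta_to_model <- function(theta, n_processes, fit_sigma) {
  procs <- vector("list", n_processes)
  deps1 <- 10^theta[[1]]; tau1 <- 10^theta[[2]]
  procs[[1]] <- hn_process(deps1, tau1, theta[[3]], theta[[4]])
  if (n_processes == 2L) {
    procs[[2]] <- hn_process(10^theta[[5]], tau1 * 10^(-theta[[6]]),
                             theta[[7]], theta[[8]])
  }
  sigma <- if (fit_sigma) 10^theta[[4 * n_processes + 1L]] else 0
  list(processes = procs, sigma_dc = sigma)
}

## Automatic initialization from the loss spectrum: tau from the peak
## location, deps from twice the peak height, sigma from the low-frequency
## slope -1 segment when present.
hn_auto_init <- function(frequency, loss, n_processes) {
  lf <- log10(frequency); ll <- log10(pmax(loss, 1e-300))
  n <- length(lf)
  head_n <- max(3L, min(6L, n %/% 4L))
  slope <- stats::coef(stats::lm(ll[1:head_n] ~ lf[1:head_n]))[[2]]
  has_sigma <- is.finite(slope) && slope < -0.5
  sigma0 <- if (has_sigma) {
    loss[[1]] * pg_constants$eps_0 * 2 * pi * frequency[[1]]
  } else 0
  ## peak search after removing the conductivity estimate
  resid_loss <- loss - sigma0 / (pg_constants$eps_0 * 2 * pi * frequency)
  ipk <- which.max(resid_loss)
  if (ipk <= 1L || ipk >= n) ipk <- which.max(loss * frequency^0.25)
  tau0 <- 1 / (2 * pi * frequency[[ipk]])
  deps0 <- max(2 * resid_loss[[ipk]], 1e-6)
  list(deps = deps0, tau = tau0, a = 0.8, b = 0.6,
       sigma = sigma0, has_sigma = has_sigma)
}

#' Fit the Havriliak-Negami model to a dielectric loss spectrum
#'
#' Least-squares fit of `log10 eps''` over the (log-spaced) measured
#' frequencies, using Levenberg-Marquardt with box constraints and
#' multi-start refinement: the automatic (or supplied) start is refit from
#' jittered starting points (+/- 0.5 decade in tau) and the best residual
#' retained. Two-process fits constrain the first process to be the slower
#' one, which breaks the label-switching symmetry.
#'
#' @param spectrum A [dielectric_spectrum()].
#' @param n_processes 1 or 2.
#' @param init Optional named list overriding the automatic start:
#'   `deps`, `tau`, `a`, `b`, `sigma` (and `deps2`, `tau2`, `a2`, `b2` for
#'   two processes).
#' @param fit_sigma Include a dc-conductivity term: `TRUE`, `FALSE`, or
#'   `"auto"` (include when the low-frequency log-log slope is below -0.5).
#' @param fit_real Also fit the real part `eps'` jointly (the default fits
#'   the loss only and uses `eps'` as a cross-check).
#' @param n_starts Number of jittered multi-starts (>= 1).
#' @param seed Seed for the start jitter; fits are deterministic given it.
#' @return An object of class `hn_fit`: `processes` (list of
#'   [hn_process()], slowest first), `eps_inf`, `sigma_dc`, `residual`
#'   (relative RMS of the loss), `covariance` (parameter covariance of the
#'   best fit, when available), and `tau_alpha` per process.
#' @export
fit_hn <- function(spectrum, n_processes = 1L, init = NULL,
                   fit_sigma = "auto", fit_real = FALSE, n_starts = 5L,
                   seed = 1L) {
  stopifnot(inherits(spectrum, "dielectric_spectrum"),
            n_processes %in% c(1L, 2L))
  f <- spectrum$frequency
  loss <- spectrum$eps_imag
  keep <- loss > 0
  if (sum(keep) < 8L) stop("too few positive-loss points to fit", call. = FALSE)
  f_fit <- f[keep]; loss_fit <- loss[keep]

  auto <- hn_auto_init(f_fit, loss_fit, n_processes)
  use_sigma <- switch(as.character(fit_sigma),
                      "TRUE" = TRUE, "FALSE" = FALSE, auto$has_sigma)
  if (!is.null(init)) for (nm in names(init)) auto[[nm]] <- init[[nm]]

  eps_inf_est <- max(1, min(spectrum$eps_real))

  theta0 <- c(log10(auto$deps), log10(auto$tau), auto$a, auto$b)
  lower <- c(-8, -16, 0.05, 0.05)
  upper <- c(8, 8, 1, 1)
  if (n_processes == 2L) {
    deps2 <- if (!is.null(init$deps2)) init$deps2 else auto$deps / 2
    tau2 <- if (!is.null(init$tau2)) init$tau2 else auto$tau / 100
    a2 <- if (!is.null(init$a2)) init$a2 else auto$a
    b2 <- if (!is.null(init$b2)) init$b2 else auto$b
    dtau0 <- max(log10(auto$tau) - log10(tau2), 0.1)
    theta0 <- c(theta0, log10(deps2), dtau0, a2, b2)
    lower <- c(lower, -8, 0, 0.05, 0.05)
    upper <- c(upper, 8, 16, 1, 1)
  }
  if (use_sigma) {
    sig0 <- if (auto$sigma > 0) auto$sigma else 1e-15
    theta0 <- c(theta0, log10(sig0))
    lower <- c(lower, -25)
    upper <- c(upper, 5)
  }

  resid_fun <- function(theta) {
    m <- hn_theta_to_model(theta, n_processes, use_sigma)
    model_eps <- hn_model(m$processes, eps_inf = eps_inf_est,
                          sigma_dc = m$sigma_dc, frequency = f_fit)
    r <- log10(pmax(-Im(model_eps), 1e-300)) - log10(loss_fit)
    if (fit_real) {
      scale_re <- stats::sd(spectrum$eps_real[keep]) + 1e-12
      r <- c(r, (Re(model_eps) - spectrum$eps_real[keep]) / scale_re)
    }
    r
  }

  old_seed <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  set.seed(seed)
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, .GlobalEnv))

  best <- NULL
  diagnostics <- character()
  for (s in seq_len(max(1L, n_starts))) {
    th <- theta0
    if (s > 1L) {
      th[[2]] <- th[[2]] + stats::runif(1, -0.5, 0.5)   # jitter tau
      if (n_processes == 2L) th[[6]] <- max(0, th[[6]] + stats::runif(1, -0.5, 0.5))
      th[[1]] <- th[[1]] + stats::runif(1, -0.2, 0.2)
    }
    th <- pmin(pmax(th, lower), upper)
    fit <- tryCatch(
      minpack.lm::nls.lm(par = th, lower = lower, upper = upper,
                         fn = resid_fun,
                         control = minpack.lm::nls.lm.control(maxiter = 400)),
      error = function(e) e)
    if (inherits(fit, "error")) {
      diagnostics <- c(diagnostics, conditionMessage(fit))
      next
    }
    if (is.null(best) || fit$deviance < best$deviance) best <- fit
  }
  if (is.null(best)) {
    stop(sprintf("HN fit failed from all starts: %s",
                 paste(unique(diagnostics), collapse = "; ")), call. = FALSE)
  }

  m <- hn_theta_to_model(best$par, n_processes, use_sigma)
  model_loss <- -Im(hn_model(m$processes, eps_inf = eps_inf_est,
                             sigma_dc = m$sigma_dc, frequency = f_fit))
  rel_rms <- sqrt(mean(((model_loss - loss_fit) / loss_fit)^2))
  covmat <- tryCatch({
    jtj <- best$hessian
    s2 <- best$deviance / max(1, length(resid_fun(best$par)) - length(best$par))
    s2 * solve(jtj)
  }, error = function(e) NULL)

  structure(
    list(processes = m$processes,
         eps_inf = eps_inf_est,
         sigma_dc = m$sigma_dc,
         residual = rel_rms,
         covariance = covmat,
         tau_alpha = vapply(m$processes, tau_alpha, numeric(1)),
         temperature = spectrum$temperature,
         n_starts = n_starts,
         converged = best$info %in% 1:4),
    class = "hn_fit")
}

#' @export
print.hn_fit <- function(x, ...) {
  cat(sprintf("<hn_fit> %d process(es), T = %.1f K (%.1f degC), rel RMS %.3g\n",
              length(x$processes), x$temperature, x$temperature - 273.15,
              x$residual))
  for (i in seq_along(x$processes)) {
    p <- x$processes[[i]]
    cat(sprintf("  [%d] deps %.4g  tau_HN %.3g s  a %.3f  b %.3f  tau_alpha %.3g s\n",
                i, p$delta_eps, p$tau_hn, p$a, p$b, x$tau_alpha[[i]]))
  }
  cat(sprintf("  eps_inf %.3f  sigma_dc %.3g S/m\n", x$eps_inf, x$sigma_dc))
  invisible(x)
}

#' Normalize a dielectric loss spectrum to unit peak
#'
#' Divides the loss by its maximum (after optional subtraction of a
#' dc-conductivity contribution, e.g. taken from a prior [fit_hn()]).
#' When the maximum sits on the first or last grid point the peak is not
#' resolved and the result carries a `boundary_peak` flag together with a
#' warning.
#'
#' @param spectrum A [dielectric_spectrum()].
#' @param sigma_dc dc conductivity to subtract before normalizing, S/m.
#' @return A list with `frequency`, `loss` (peak value exactly 1),
#'   `peak_frequency`, `eps_imag_max` and logical `boundary_peak`, of class
#'   `normalized_loss`.
#' @export
normalize_loss <- function(spectrum, sigma_dc = 0) {
  stopifnot(inherits(spectrum, "dielectric_spectrum"))
  loss <- spectrum$eps_imag
  if (sigma_dc > 0) {
    loss <- loss - sigma_dc / (pg_constants$eps_0 * 2 * pi * spectrum$frequency)
  }
  if (all(loss <= 0)) stop("no positive loss after conductivity subtraction", call. = FALSE)
  ipk <- which.max(loss)
  boundary <- ipk == 1L || ipk == length(loss)
  if (boundary) {
    warning("loss maximum at grid boundary; peak not resolved", call. = FALSE)
  }
  structure(list(frequency = spectrum$frequency, loss = loss / loss[[ipk]],
                 peak_frequency = spectrum$frequency[[ipk]],
                 eps_imag_max = loss[[ipk]],
                 boundary_peak = boundary,
                 temperature = spectrum$temperature),
            class = "normalized_loss")
}
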