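## Validated containers for the three instrument-trace classes.

#' One temperature's frequency sweep of complex permittivity
#'
#' @param frequency Frequencies in Hz, strictly increasing, >= 20 points.
#' @param eps_real Real part of the complex permittivity.
#' @param eps_imag Dielectric loss (imaginary part, as a positive loss).
#' @param temperature Sample temperature, K.
#' @return An object of class `dielectric_spectrum`.
#' @export
dielectric_spectrum <- function(frequency, eps_real, eps_imag, temperature) {
  stopifnot(length(frequency) == length(eps_real),
            length(frequency) == length(eps_imag))
  if (length(frequency) < 20L) {
    stop("spectrum needs at least 20 frequency points", call. = FALSE)
  }
  if (anyNA(frequency) || anyNA(eps_real) || anyNA(eps_imag)) {
    stop("spectrum contains NA values", call. = FALSE)
  }
  if (any(diff(frequency) <= 0)) {
    stop("frequencies must be strictly increasing", call. = FALSE)
  }
  if (any(frequency <= 0)) stop("frequencies must be positive", call. = FALSE)
  stopifnot(is.numeric(temperature), length(temperature) == 1L, temperature > 0)
  structure(list(frequency = frequency, eps_real = eps_real,
                 eps_imag = eps_imag, temperature = temperature),
            class = "dielectric_spectrum")
}

#' @export
print.dielectric_spectrum <- function(x, ...) {
  cat(sprintf("<dielectric_spectrum> %d points, %.2g-%.2g Hz, T = %.1f K (%.1f degC)\n",
              length(x$frequency), min(x$frequency), max(x$frequency),
              x$temperature, x$temperature - 273.15))
  invisible(x)
}

#' A DSC heating trace
#'
#' @param temperature Temperature axis in degC, strictly increasing,
#'   >= 50 points.
#' @param signal Apparent specific heat, J/(g K), or heat flow, W/g,
#'   depending on `signal_kind`; per gram of mixture.
#' @param heating_rate Heating rate, K/min.
#' @param signal_kind `"cp"` or `"heat_flow"`.
#' @param mass_mg Sample mass, mg (kept for provenance; signals are
#'   already mass-normalised).
#' @return An object of class `thermogram`.
#' @export
thermogram <- function(temperature, signal, heating_rate, signal_kind = "cp",
                       mass_mg = NA_real_) {
  stopifnot(length(temperature) == length(signal))
  if (length(temperature) < 50L) {
    stop("thermogram needs at least 50 samples per segment", call. = FALSE)
  }
  if (anyNA(temperature) || anyNA(signal)) {
    stop("thermogram contains NA values", call. = FALSE)
  }
  if (any(diff(temperature) <= 0)) {
    stop("temperature must be strictly increasing for a heating segment", call. = FALSE)
  }
  stopifnot(is.numeric(heating_rate), length(heating_rate) == 1L, heating_rate > 0)
  if (!signal_kind %in% c("cp", "heat_flow")) {
    stop("signal_kind must be 'cp' or 'heat_flow'", call. = FALSE)
  }
  structure(list(temperature = temperature, signal = signal,
                 heating_rate = heating_rate, signal_kind = signal_kind,
                 mass_mg = mass_mg),
            class = "thermogram")
}

#' @export
print.thermogram <- function(x, ...) {
  cat(sprintf("<thermogram> %d points, %.1f-%.1f degC (%.1f-%.1f K), %g K/min, signal '%s'\n",
              length(x$temperature), min(x$temperature), max(x$temperature),
              min(x$temperature) + 273.15, max(x$temperature) + 273.15,
              x$heating_rate, x$signal_kind))
  invisible(x)
}

## Convert a thermogram signal to apparent specific heat J/(g K) in place.
thermogram_as_cp <- function(tg) {
  if (tg$signal_kind == "cp") return(tg)
  ## W/g divided by K/s gives J/(g K)
  rate_K_per_s <- tg$heating_rate / 60
  tg$signal <- tg$signal / rate_K_per_s
  tg$signal_kind <- "cp"
  tg
}

#' An isothermal crystallization trace
#'
#' @param time Time since the start of annealing, s, strictly increasing,
#'   >= 8 points, starting at or after 0.
#' @param observable Static permittivity (`kind = "bds"`) or crystallinity
#'   in `[0, 1]` (`kind = "dsc"`).
#' @param kind `"bds"` or `"dsc"`.
#' @param temperature Annealing temperature, K.
#' @return An object of class `crystallization_trace`.
#' @export
crystallization_trace <- function(time, observable, kind = c("bds", "dsc"),
                                  temperature) {
  kind <- match.arg(kind)
  stopifnot(length(time) == length(observable))
  if (length(time) < 8L) stop("trace needs at least 8 points", call. = FALSE)
  if (anyNA(time) || anyNA(observable)) stop("trace contains NA values", call. = FALSE)
  if (any(diff(time) <= 0)) stop("time must be strictly increasing", call. = FALSE)
  if (time[[1L]] < 0) stop("time must start at or after 0", call. = FALSE)
  stopifnot(is.numeric(temperature), length(temperature) == 1L, temperature > 0)
  structure(list(time = time, observable = observable, kind = kind,
                 temperature = temperature),
            class = "crystallization_trace")
}

#' @export
print.crystallization_trace <- function(x, ...) {
  cat(sprintf("<crystallization_trace> %s, %d points over %.0f s, T = %.1f K (%.1f degC)\n",
              x$kind, length(x$time), max(x$time), x$temperature,
              x$temperature - 273.15))
  invisible(x)
}
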