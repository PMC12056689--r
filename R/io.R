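## CSV readers/writers for the three instrument-trace classes. All files
## use a comment-header dialect: lines starting with '#' carry
## 'key=value' metadata, followed by a regular CSV header and data rows.
## Temperatures are stored in the unit the key names (..._K or ..._C).

read_csv_with_meta <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  lines <- readLines(path)
  meta_idx <- grep("^#", lines)
  meta_idx <- meta_idx[meta_idx == seq_along(meta_idx)]  # leading block only
  meta <- list()
  for (ln in lines[meta_idx]) {
    kv <- sub("^#\\s*", "", ln)
    eq <- regexpr("=", kv, fixed = TRUE)
    if (eq < 0) {
      stop(sprintf("format error: metadata line without '=': '%s'", ln), call. = FALSE)
    }
    key <- trimws(substr(kv, 1L, eq - 1L))
    val <- trimws(substr(kv, eq + 1L, nchar(kv)))
    meta[[key]] <- val
  }
  body <- lines[setdiff(seq_along(lines), meta_idx)]
  df <- utils::read.csv(text = paste(body, collapse = "\n"),
                        stringsAsFactors = FALSE)
  list(meta = meta, data = df)
}

write_csv_with_meta <- function(df, meta, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (key in names(meta)) {
    writeLines(sprintf("# %s=%s", key, format(meta[[key]], scientific = FALSE)), con)
  }
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}

meta_number <- function(meta, key, path, locale_comma = FALSE) {
  if (is.null(meta[[key]])) {
    stop(sprintf("format error: missing metadata header '# %s=' in %s", key, path),
         call. = FALSE)
  }
  val <- meta[[key]]
  if (locale_comma) val <- gsub(",", ".", val, fixed = TRUE)
  num <- suppressWarnings(as.numeric(val))
  if (is.na(num)) {
    stop(sprintf("format error: metadata '%s' is not numeric in %s", key, path),
         call. = FALSE)
  }
  num
}

check_strictly_increasing <- function(x, what, path) {
  bad <- which(diff(x) <= 0)
  if (length(bad)) {
    stop(sprintf("data error: %s not strictly increasing in %s (first inversion at row %d)",
                 what, path, bad[[1L]] + 1L), call. = FALSE)
  }
  if (anyNA(x)) stop(sprintf("data error: NA in %s of %s", what, path), call. = FALSE)
  invisible(x)
}

parse_numeric_cols <- function(df, cols, locale_comma, path) {
  for (cc in cols) {
    if (!cc %in% names(df)) {
      stop(sprintf("format error: missing column '%s' in %s", cc, path), call. = FALSE)
    }
    v <- df[[cc]]
    if (is.character(v)) {
      if (locale_comma) v <- gsub(",", ".", v, fixed = TRUE)
      v <- suppressWarnings(as.numeric(v))
    }
    if (anyNA(v)) stop(sprintf("data error: non-numeric value in column '%s' of %s", cc, path), call. = FALSE)
    df[[cc]] <- v
  }
  df
}

#' Read a dielectric spectrum from CSV
#'
#' Expected columns `frequency_Hz, eps_real, eps_imag` and a
#' `# temperature_K=` metadata header. Frequencies must be strictly
#' increasing and at least 20 points long.
#'
#' @param path File path.
#' @param locale_comma Accept comma decimal separators (both in metadata
#'   and data columns).
#' @return A [dielectric_spectrum()].
#' @export
read_spectrum_csv <- function(path, locale_comma = FALSE) {
  parsed <- read_csv_with_meta(path)
  temp <- meta_number(parsed$meta, "temperature_K", path, locale_comma)
  df <- parse_numeric_cols(parsed$data, c("frequency_Hz", "eps_real", "eps_imag"),
                           locale_comma, path)
  check_strictly_increasing(df$frequency_Hz, "frequency_Hz", path)
  dielectric_spectrum(frequency = df$frequency_Hz, eps_real = df$eps_real,
                      eps_imag = df$eps_imag, temperature = temp)
}

#' Write a dielectric spectrum to CSV
#' @param spectrum A [dielectric_spectrum()].
#' @param path Output file path.
#' @export
write_spectrum_csv <- function(spectrum, path) {
  write_csv_with_meta(
    data.frame(frequency_Hz = spectrum$frequency, eps_real = spectrum$eps_real,
               eps_imag = spectrum$eps_imag),
    list(temperature_K = spectrum$temperature), path)
}

#' Read a DSC thermogram from CSV
#'
#' Expected columns `temperature_C, signal` plus metadata headers
#' `# heating_rate_K_per_min=`, `# signal_kind=` (`cp` for apparent
#' specific heat in J/(g K), `heat_flow` for W/g) and `# mass_mg=`.
#' Traces without complete metadata are rejected, never guessed.
#'
#' @inheritParams read_spectrum_csv
#' @return A [thermogram()].
#' @export
read_thermogram_csv <- function(path, locale_comma = FALSE) {
  parsed <- read_csv_with_meta(path)
  rate <- meta_number(parsed$meta, "heating_rate_K_per_min", path, locale_comma)
  if (is.null(parsed$meta$signal_kind)) {
    stop(sprintf("format error: missing metadata header '# signal_kind=' in %s", path),
         call. = FALSE)
  }
  mass <- meta_number(parsed$meta, "mass_mg", path, locale_comma)
  df <- parse_numeric_cols(parsed$data, c("temperature_C", "signal"), locale_comma, path)
  check_strictly_increasing(df$temperature_C, "temperature_C", path)
  thermogram(temperature = df$temperature_C, signal = df$signal,
             heating_rate = rate, signal_kind = parsed$meta$signal_kind,
             mass_mg = mass)
}

#' Write a DSC thermogram to CSV
#' @param tg A [thermogram()].
#' @param path Output file path.
#' @export
write_thermogram_csv <- function(tg, path) {
  write_csv_with_meta(
    data.frame(temperature_C = tg$temperature, signal = tg$signal),
    list(heating_rate_K_per_min = tg$heating_rate, signal_kind = tg$signal_kind,
         mass_mg = tg$mass_mg), path)
}

#' Read an isothermal crystallization trace from CSV
#'
#' Expected columns `time_s, observable` plus `# kind=` (`bds` for a
#' static-permittivity trace, `dsc` for a crystallinity trace) and
#' `# temperature_K=` headers.
#'
#' @inheritParams read_spectrum_csv
#' @return A [crystallization_trace()].
#' @export
read_trace_csv <- function(path, locale_comma = FALSE) {
  parsed <- read_csv_with_meta(path)
  if (is.null(parsed$meta$kind)) {
    stop(sprintf("format error: missing metadata header '# kind=' in %s", path),
         call. = FALSE)
  }
  temp <- meta_number(parsed$meta, "temperature_K", path, locale_comma)
  df <- parse_numeric_cols(parsed$data, c("time_s", "observable"), locale_comma, path)
  check_strictly_increasing(df$time_s, "time_s", path)
  crystallization_trace(time = df$time_s, observable = df$observable,
                        kind = parsed$meta$kind, temperature = temp)
}

#' Write an isothermal crystallization trace to CSV
#' @param trace A [crystallization_trace()].
#' @param path Output file path.
#' @export
write_trace_csv <- function(trace, path) {
  write_csv_with_meta(
    data.frame(time_s = trace$time, observable = trace$observable),
    list(kind = trace$kind, temperature_K = trace$temperature), path)
}
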