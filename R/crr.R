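## Donth fluctuation sizing of the cooperatively rearranging region (CRR)
## at the glass transition:
##   L = [ k_B T_g^2 (1/C_pg - 1/C_pl) / (rho dTg^2) ]^(1/3)
## with T_g the onset glass-transition temperature (K), dTg half the
## onset-to-end transition width (K), rho the glass density (kg/m^3) and
## the specific heats in J/(kg K). The ambient glass density is used, as
## the density at T_g is rarely known.

#' Cooperatively-rearranging-region size (Donth relation)
#'
#' @param tg_onset Onset glass-transition temperature, K.
#' @param half_width Half of the onset-to-end transition width, K.
#' @param density Glass density, kg/m^3.
#' @param cp_glass,cp_liquid Specific heats of glass and supercooled
#'   liquid, J/(kg K); `cp_liquid >= cp_glass`. Equal values give a
#'   degenerate zero-size CRR, flagged with a warning.
#' @return CRR characteristic length, nm.
#' @examples
#' crr_size(331, 2, 1410, 1620, 2070)  # ~3.30 nm
#' @export
crr_size <- function(tg_onset, half_width, density, cp_glass, cp_liquid) {
  stopifnot(tg_onset > 0, half_width > 0, density > 0, cp_glass > 0,
            cp_liquid > 0)
  if (cp_liquid < cp_glass) {
    stop("cp_liquid must be at least cp_glass", call. = FALSE)
  }
  if (cp_liquid == cp_glass) {
    warning("cp_glass equals cp_liquid: degenerate CRR of size 0", call. = FALSE)
    return(0)
  }
  d_inv_cp <- 1 / cp_glass - 1 / cp_liquid
  L_m <- (pg_constants$k_B * tg_onset^2 * d_inv_cp /
            (density * half_width^2))^(1 / 3)
  L_m * 1e9
}

#' CRR size from a DSC glass-transition result and material constants
#'
#' Convenience wrapper converting the laboratory units of
#' [detect_glass_transition()] (degC) and [glass_spec()] (g/cm^3,
#' J/(g K)) to SI before applying [crr_size()].
#'
#' @param gt A `glass_transition` from [detect_glass_transition()].
#' @param substance A [glass_spec()].
#' @return CRR characteristic length, nm.
#' @export
crr_from_dsc <- function(gt, substance) {
  stopifnot(inherits(gt, "glass_transition"), inherits(substance, "glass_spec"))
  crr_size(tg_onset = gt$tg_onset + 273.15,
           half_width = gt$half_width,
           density = substance$glass_density * 1000,   # g/cm3 -> kg/m3
           cp_glass = substance$cp_glass * 1000,       # J/(g K) -> J/(kg K)
           cp_liquid = substance$cp_liquid * 1000)
}
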