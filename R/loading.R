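## Geometric drug-loading model: how much silica is needed so that every
## drug molecule either sits in a surface monolayer or fits inside the pore
## volume. The molecule is idealised as a cube of the bulk glass density;
## its face area is the adsorption footprint.

#' Per-molecule adsorption footprint under the cubic-molecule assumption
#'
#' The molecular volume is `V = M / (rho * N_A)`; a cube of that volume
#' presents a face of area `V^(2/3)`, taken as the area one adsorbed
#' molecule occupies on the silica surface.
#'
#' @param substance A [glass_spec()].
#' @return Footprint in nm^2 per molecule.
#' @examples
#' cel <- glass_spec("celecoxib", glass_density = 1.41,
#'                   cp_glass = 1.62, cp_liquid = 2.07, tg_onset = 58)
#' molecular_footprint(cel)  # ~0.59 nm^2
#' @export
molecular_footprint <- function(substance) {
  stopifnot(inherits(substance, "glass_spec"))
  ## volume in nm^3: (g/mol) / ((g/cm3) * (1/mol)) = cm3 -> x 1e21 nm3
  v_nm3 <- substance$molar_mass / (substance$glass_density * pg_constants$N_A) * 1e21
  v_nm3^(2 / 3)
}

#' Theoretical monolayer capacity of a silica grade
#'
#' Number of drug molecules per gram of silica when the whole surface is
#' densely packed with a monolayer: surface area divided by the
#' per-molecule footprint.
#'
#' @param silica A [silica_spec()].
#' @param substance A [glass_spec()].
#' @return Capacity in molecules per gram of silica.
#' @export
monolayer_capacity <- function(silica, substance) {
  stopifnot(inherits(silica, "silica_spec"))
  (silica$surface_area * 1e18) / molecular_footprint(substance)  # nm2/g / nm2
}

#' Drug mass adsorbable as a monolayer, per gram of silica
#'
#' @inheritParams monolayer_capacity
#' @return Mass ratio, g drug per g silica.
#' @export
monolayer_mass_ratio <- function(silica, substance) {
  monolayer_capacity(silica, substance) * substance$molar_mass / pg_constants$N_A
}

#' Silica mass fraction giving monolayer adsorption sites for all drug
#'
#' With `r` the drug mass adsorbable per gram of silica, a mixture whose
#' silica fraction is `f = 1 / (1 + r)` offers exactly one monolayer site
#' per molecule.
#'
#' @inheritParams monolayer_capacity
#' @return Dimensionless silica mass fraction in (0, 1].
#' @export
ms_fraction_for_monolayer <- function(silica, substance) {
  1 / (1 + monolayer_mass_ratio(silica, substance))
}

#' Silica mass fraction whose pore volume holds all drug as glass
#'
#' A gram of silica offers `V_p` mL of pores, accommodating `V_p * rho`
#' grams of drug glass; complete confinement needs a silica fraction
#' `f = 1 / (1 + V_p * rho)`.
#'
#' @inheritParams monolayer_capacity
#' @return Dimensionless silica mass fraction in (0, 1].
#' @export
ms_fraction_for_pore_filling <- function(silica, substance) {
  1 / (1 + silica$pore_volume * substance$glass_density)
}

#' Monolayer-site occupancy at a given silica load
#'
#' Interprets a silica mass fraction (for example, the load at which the
#' drug's glass transition is extrapolated to vanish) as a drug/silica mass
#' ratio and expresses it relative to the monolayer capacity. An occupancy
#' of 1 means exactly one monolayer's worth of drug per gram of silica.
#'
#' @inheritParams monolayer_capacity
#' @param ms_mass_fraction Silica mass fraction strictly inside (0, 1).
#' @return Dimensionless occupancy in `[0, Inf)`.
#' @export
monolayer_occupancy <- function(silica, substance, ms_mass_fraction) {
  if (!is.numeric(ms_mass_fraction) || length(ms_mass_fraction) != 1L ||
      is.na(ms_mass_fraction) || ms_mass_fraction <= 0 || ms_mass_fraction >= 1) {
    stop("ms_mass_fraction must lie strictly inside (0, 1)", call. = FALSE)
  }
  ratio <- (1 - ms_mass_fraction) / ms_mass_fraction
  ratio / monolayer_mass_ratio(silica, substance)
}

#' Full loading-geometry report for one silica/substance pair
#'
#' @inheritParams monolayer_capacity
#' @param ms_fraction_full_rigid Optional silica mass fraction at which all
#'   drug is immobilised (e.g. from [extrapolate_full_rigid_load()]); when
#'   given, the monolayer occupancy at that load is reported too.
#' @return An object of class `loading_report`: footprint (nm^2),
#'   monolayer capacity (molecules/g), monolayer mass ratio (g/g), and the
#'   silica fractions required for monolayer coverage and pore confinement.
#' @export
loading_report <- function(silica, substance, ms_fraction_full_rigid = NULL) {
  rep <- list(
    silica = silica$name,
    substance = substance$name,
    footprint_nm2 = molecular_footprint(substance),
    monolayer_capacity = monolayer_capacity(silica, substance),
    monolayer_mass_ratio = monolayer_mass_ratio(silica, substance),
    ms_fraction_monolayer = ms_fraction_for_monolayer(silica, substance),
    ms_fraction_pore_filling = ms_fraction_for_pore_filling(silica, substance))
  if (!is.null(ms_fraction_full_rigid)) {
    rep$occupancy_at <- vapply(ms_fraction_full_rigid, function(f)
      monolayer_occupancy(silica, substance, f), numeric(1))
    names(rep$occupancy_at) <- format(ms_fraction_full_rigid)
  }
  structure(rep, class = "loading_report")
}

#' @export
print.loading_report <- function(x, ...) {
  cat(sprintf("<loading_report> %s on %s\n", x$substance, x$silica))
  cat(sprintf("  footprint:            %.4f nm2/molecule\n", x$footprint_nm2))
  cat(sprintf("  monolayer capacity:   %.3e molecules/g\n", x$monolayer_capacity))
  cat(sprintf("  monolayer mass ratio: %.4f g drug / g MS\n", x$monolayer_mass_ratio))
  cat(sprintf("  MS for monolayer:     %.1f %%\n", 100 * x$ms_fraction_monolayer))
  cat(sprintf("  MS for pore filling:  %.1f %%\n", 100 * x$ms_fraction_pore_filling))
  if (!is.null(x$occupancy_at)) {
    for (nm in names(x$occupancy_at)) {
      cat(sprintf("  occupancy at MS=%s:  %.3f\n", nm, x$occupancy_at[[nm]]))
    }
  }
  invisible(x)
}
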