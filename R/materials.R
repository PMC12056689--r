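## Material specifications: mesoporous silica grades, glass-forming drug
## substances and their binary mixtures. Config files use the conventional
## laboratory units (m2/g, nm, mL/g, um, g/mol, g/cm3, J/(g K), degC); the
## constructors keep those units on the object and downstream code converts
## to SI at the point of use.

stop_validation <- function(field, msg) {
  stop(sprintf("invalid %s: %s", field, msg), call. = FALSE)
}

check_positive <- function(x, field) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0) {
    stop_validation(field, "must be a single positive finite number")
  }
  invisible(x)
}

#' Mesoporous silica specification
#'
#' Geometric and surface properties of one silica grade. A consistency
#' check compares the hydraulic pore diameter implied by a cylindrical-pore
#' model, 4 V_p / SA, against the declared pore diameter and warns (never
#' errors) when they disagree by more than a factor of two.
#'
#' @param name Label for the grade, e.g. `"SYL350"`.
#' @param surface_area Specific surface area, m^2/g.
#' @param pore_diameter Effective pore diameter, nm.
#' @param pore_volume Specific pore volume, mL/g.
#' @param particle_diameter Particle diameter, um.
#' @return An object of class `silica_spec`.
#' @examples
#' silica_spec("SYL350", surface_area = 300, pore_diameter = 21,
#'             pore_volume = 1.6, particle_diameter = 4)
#' @export
silica_spec <- function(name, surface_area, pore_diameter, pore_volume,
                        particle_diameter) {
  stopifnot(is.character(name), length(name) == 1L)
  check_positive(surface_area, "surface_area")
  check_positive(pore_diameter, "pore_diameter")
  check_positive(pore_volume, "pore_volume")
  check_positive(particle_diameter, "particle_diameter")
  ## hydraulic diameter in nm: 4 * (mL/g -> nm3/g) / (m2/g -> nm2/g)
  d_hyd <- 4 * (pore_volume * 1e21) / (surface_area * 1e18)
  if (d_hyd < 0.5 * pore_diameter || d_hyd > 2 * pore_diameter) {
    warning(sprintf(
      "%s: hydraulic pore diameter 4*Vp/SA = %.2f nm is not within [0.5x, 2x] of the declared %.2f nm",
      name, d_hyd, pore_diameter), call. = FALSE)
  }
  structure(
    list(name = name, surface_area = surface_area,
         pore_diameter = pore_diameter, pore_volume = pore_volume,
         particle_diameter = particle_diameter),
    class = "silica_spec")
}

#' Glass-forming substance specification
#'
#' Thermophysical parameters of the drug glass: molar mass, true (glass)
#' density, specific heats of the glass and the supercooled liquid, and the
#' onset glass-transition temperature.
#'
#' @param name Label, e.g. `"celecoxib"`.
#' @param molar_mass g/mol. Defaults to celecoxib (381.37 g/mol).
#' @param glass_density g/cm^3.
#' @param cp_glass,cp_liquid Specific heat capacity of the glass and the
#'   supercooled liquid, J/(g K); `cp_liquid` must exceed `cp_glass`.
#' @param tg_onset Onset glass-transition temperature, degC.
#' @return An object of class `glass_spec`.
#' @examples
#' glass_spec("celecoxib", glass_density = 1.41,
#'            cp_glass = 1.62, cp_liquid = 2.07, tg_onset = 58)
#' @export
glass_spec <- function(name, molar_mass = pg_constants$celecoxib_molar_mass,
                       glass_density, cp_glass, cp_liquid, tg_onset) {
  stopifnot(is.character(name), length(name) == 1L)
  check_positive(molar_mass, "molar_mass")
  check_positive(glass_density, "glass_density")
  check_positive(cp_glass, "cp_glass")
  check_positive(cp_liquid, "cp_liquid")
  if (cp_liquid <= cp_glass) {
    stop_validation("cp_liquid", "must exceed cp_glass")
  }
  if (!is.numeric(tg_onset) || length(tg_onset) != 1L || !is.finite(tg_onset)) {
    stop_validation("tg_onset", "must be a single finite number (degC)")
  }
  structure(
    list(name = name, molar_mass = molar_mass, glass_density = glass_density,
         cp_glass = cp_glass, cp_liquid = cp_liquid, tg_onset = tg_onset),
    class = "glass_spec")
}

#' Binary drug/silica mixture
#'
#' Mixing ratios follow the convention of quoting the mass proportion of
#' the mesoporous silica, so `ms_mass_fraction = 0.75` means 25 % drug by
#' mass. Both limits (pure drug, pure silica) are valid.
#'
#' @param substance A [glass_spec()].
#' @param silica A [silica_spec()].
#' @param ms_mass_fraction Silica mass fraction in `[0, 1]`.
#' @return An object of class `mixture_spec`.
#' @export
mixture_spec <- function(substance, silica, ms_mass_fraction) {
  stopifnot(inherits(substance, "glass_spec"), inherits(silica, "silica_spec"))
  if (!is.numeric(ms_mass_fraction) || length(ms_mass_fraction) != 1L ||
      is.na(ms_mass_fraction) || ms_mass_fraction < 0 || ms_mass_fraction > 1) {
    stop_validation("ms_mass_fraction", "must lie in [0, 1]")
  }
  structure(
    list(substance = substance, silica = silica,
         ms_mass_fraction = ms_mass_fraction,
         drug_mass_fraction = 1 - ms_mass_fraction),
    class = "mixture_spec")
}

#' @export
print.silica_spec <- function(x, ...) {
  cat(sprintf("<silica_spec> %s: SA %g m2/g, pore %g nm, Vp %g mL/g, particle %g um\n",
              x$name, x$surface_area, x$pore_diameter, x$pore_volume,
              x$particle_diameter))
  invisible(x)
}

#' @export
print.glass_spec <- function(x, ...) {
  cat(sprintf("<glass_spec> %s: M %g g/mol, rho %g g/cm3, Cpg %g / Cpl %g J/(g K), Tg %g degC\n",
              x$name, x$molar_mass, x$glass_density, x$cp_glass, x$cp_liquid,
              x$tg_onset))
  invisible(x)
}

#' @export
print.mixture_spec <- function(x, ...) {
  cat(sprintf("<mixture_spec> %s + %s, %.0f%% MS\n", x$substance$name,
              x$silica$name, 100 * x$ms_mass_fraction))
  invisible(x)
}

.silica_keys <- c("name", "surface_area", "pore_diameter", "pore_volume",
                  "particle_diameter")
.glass_keys <- c("name", "molar_mass", "glass_density", "cp_glass",
                 "cp_liquid", "tg_onset")

#' Load material specifications from a YAML config
#'
#' The config document has two optional top-level lists, `silicas` and
#' `substances`, each entry a flat mapping of the constructor arguments.
#' Unknown keys are rejected by name; missing required keys raise a
#' configuration error naming the key. Empty or absent lists are allowed.
#'
#' @param config_text A YAML string, or a file path when `is_path = TRUE`.
#' @param is_path Interpret `config_text` as a file path.
#' @return A list with components `silicas` (list of [silica_spec()]) and
#'   `substances` (list of [glass_spec()]).
#' @examples
#' cfg <- "
#' silicas:
#'   - {name: SYL350, surface_area: 300, pore_diameter: 21,
#'      pore_volume: 1.6, particle_diameter: 4}
#' substances:
#'   - {name: celecoxib, molar_mass: 381.37, glass_density: 1.41,
#'      cp_glass: 1.62, cp_liquid: 2.07, tg_onset: 58}
#' "
#' load_materials(cfg)
#' @export
load_materials <- function(config_text, is_path = FALSE) {
  doc <- if (is_path) yaml::read_yaml(config_text) else yaml::yaml.load(config_text)
  if (is.null(doc)) doc <- list()
  if (!is.list(doc)) stop("configuration error: document is not a mapping", call. = FALSE)
  extra <- setdiff(names(doc), c("silicas", "substances"))
  if (length(extra)) {
    stop(sprintf("configuration error: unknown top-level key '%s'", extra[[1L]]),
         call. = FALSE)
  }
  parse_entries <- function(entries, keys, ctor, what, optional = character()) {
    lapply(entries, function(e) {
      if (!is.list(e)) stop(sprintf("configuration error: %s entry is not a mapping", what), call. = FALSE)
      unknown <- setdiff(names(e), keys)
      if (length(unknown)) {
        stop(sprintf("configuration error: unknown key '%s' in %s entry", unknown[[1L]], what), call. = FALSE)
      }
      missing <- setdiff(setdiff(keys, optional), names(e))
      if (length(missing)) {
        stop(sprintf("configuration error: missing key '%s' in %s entry", missing[[1L]], what), call. = FALSE)
      }
      do.call(ctor, e)
    })
  }
  list(
    silicas = parse_entries(doc$silicas, .silica_keys, silica_spec, "silica"),
    substances = parse_entries(doc$substances, .glass_keys, glass_spec,
                               "substance", optional = "molar_mass"))
}

#' Serialize material specs back to YAML
#'
#' Inverse of [load_materials()]: the emitted document parses back to
#' field-identical specs.
#'
#' @param silicas List of [silica_spec()] objects.
#' @param substances List of [glass_spec()] objects.
#' @return A YAML string.
#' @export
materials_to_yaml <- function(silicas = list(), substances = list()) {
  yaml::as.yaml(list(
    silicas = lapply(silicas, function(s) s[.silica_keys]),
    substances = lapply(substances, function(s) s[.glass_keys])))
}
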