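## Physical constants (CODATA 2018 exact values where defined).

#' Physical constants used throughout the package
#'
#' Avogadro's number (1/mol), Boltzmann's constant (J/K) and the vacuum
#' permittivity (F/m), plus the default molar mass of celecoxib (g/mol),
#' which ships as a documented, always-overridable constant.
#'
#' @format A named list with elements `N_A`, `k_B`, `eps_0`, `celecoxib_molar_mass`.
#' @export
pg_constants <- list(
  N_A   = 6.02214076e23,
  k_B   = 1.380649e-23,
  eps_0 = 8.8541878128e-12,
  celecoxib_molar_mass = 381.37
)
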