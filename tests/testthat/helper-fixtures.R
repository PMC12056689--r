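# Reference fixtures shared across the suite. These mirror the regime the
# package targets: celecoxib glass (Tg onset ~58 degC, glass density
# 1.41 g/cm3, Cp step ~0.45 J/(g K), specific heats 1.62/2.07 J/(g K))
# mixed with two commercial silica grades, a wide-pore one (300 m2/g,
# 21 nm, 1.6 mL/g) and a narrow-pore one (700 m2/g, 2.5 nm, 0.44 mL/g).

fix_syl350 <- function() silica_spec("SYL350", surface_area = 300,
                                     pore_diameter = 21, pore_volume = 1.6,
                                     particle_diameter = 4)

fix_syl730 <- function() silica_spec("SYL730", surface_area = 700,
                                     pore_diameter = 2.5, pore_volume = 0.44,
                                     particle_diameter = 4)

fix_celecoxib <- function() glass_spec("celecoxib", molar_mass = 381.37,
                                       glass_density = 1.41, cp_glass = 1.62,
                                       cp_liquid = 2.07, tg_onset = 58)

# Isothermal crystallization reference kinetics (pure drug at 95 degC):
# k = 1.59e-7 s^-n, d = 907 s, n = 1.8.
fix_avrami_truth <- function() list(k = 1.59e-7, d = 907, n = 1.8)

# Canonical materials config document matching the fixtures above.
fix_materials_yaml <- function() {
  materials_to_yaml(silicas = list(fix_syl350(), fix_syl730()),
                    substances = list(fix_celecoxib()))
}

# Fraction model that plants an exactly straight per-gram-of-mixture
# delta_cp line with root at `root`: delta_cp(f) = pure * (1 - f/root)
# requires rigid(f) = 100 * (1 - (1 - f/root) / (1 - f)).
fix_linear_dcp_model <- function(root) {
  function(f) c(100 * (1 - (1 - f / root) / (1 - f)), 0)
}

# Independent numeric HN loss-peak locator: dense golden-section search on
# the forward model only (never the tau_alpha closed form).
numeric_loss_peak_tau <- function(process) {
  lt <- log10(process$tau_hn)
  opt <- optimize(function(lf) {
    Im(hn_model(process, eps_inf = 1, sigma_dc = 0, frequency = 10^lf))
  }, interval = c(-lt - 9, -lt + 9), tol = 1e-10)
  1 / (2 * pi * 10^opt$minimum)
}
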