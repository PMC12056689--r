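---
title: "Methods: dielectric and calorimetric analysis of silica-confined drug glasses"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: dielectric and calorimetric analysis of silica-confined drug glasses}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(poreglass)
```

## The physical picture

An amorphous drug formulated with mesoporous silica (MS) partitions into
three populations with distinct calorimetric signatures:

* **rigid** — immobilised at the silica surface; shows no glass
  transition at all;
* **intermediate** — undergoes a glass transition but never cold-
  crystallizes on heating;
* **free** — bulk-like; shows both the glass transition and cold
  crystallization.

`poreglass` quantifies this partition and the molecular mobility behind
it from two instrument families: DSC heating traces and broadband
dielectric spectra, plus isothermal crystallization monitoring by either
technique. A geometric loading model connects the partition to the
carrier's surface area and pore volume. All units at the user interface
are the laboratory conventions (°C, J/(g K), g/cm³, mL/g, m²/g, nm);
conversions to SI happen once, at the point of use, because the Donth
formula mixes Boltzmann's constant with specific heats and fixing the
internal convention prevents unit bugs.

## Loading geometry

The adsorption footprint idealises a molecule of molar mass $M$ and glass
density $\rho$ as a cube: $V = M/(\rho N_A)$, footprint $= V^{2/3}$. For
celecoxib ($M = 381.37$ g/mol, $\rho = 1.41$ g/cm³, the default molar
mass shipped with the package) this gives 0.59 nm². Dividing the silica
surface area by the footprint gives the monolayer capacity; converting
to a drug mass per gram of silica $r$ gives the silica mass fraction
$f = 1/(1+r)$ at which every molecule has a monolayer site. Similarly
$f = 1/(1 + V_p \rho)$ is the fraction at which the pore volume $V_p$
holds all drug as glass. `monolayer_occupancy()` re-expresses any
observed silica load (for example the load at which the glass transition
is extrapolated to vanish) as a fraction of one monolayer. A
back-calculation of *unfilled pore volume* from these quantities is
deliberately not provided: the arithmetic requires assumptions about
where the non-rigid drug resides that the observables do not constrain.

The model is a cubic idealisation, not an adsorption isotherm; its
purpose is order-of-magnitude bookkeeping of surface sites versus pore
volume, and the package reports fractions dimensionlessly, converting to
percent only at presentation.

## DSC feature extraction

`detect_glass_transition()` uses the standard tangent construction:
linear baselines are fitted to the outer 20 % of the search window on
each side, a tangent is drawn at the maximum-slope point of the
(Savitzky–Golay-smoothed) trace, and onset/end are the tangent-baseline
intersections. $\Delta C_p$ is the vertical separation of the
extrapolated baselines at the midpoint, which makes the measurement
invariant to any linear baseline. Smoothing (default window 11 points,
order 2) is necessary because slope tangents on noisy traces are
ill-posed; the window is configurable and should stay well below the
transition width in samples. The detection threshold for a real step
defaults to 0.02 J/(g K), below the smallest steps of interest here;
flat traces raise an error rather than returning noise. The onset/end
convention (rather than half-height) was chosen because the downstream
Donth analysis consumes the onset temperature and the onset-to-end
width. Heat-flow traces are converted to an apparent-$C_p$ basis through
the declared heating rate; traces without complete metadata are rejected
rather than guessed.

`integrate_peak()` subtracts the straight line joining the trace at the
window endpoints (averaged over 3 samples each for noise robustness).
On a $C_p$ basis the area is already J/g. No correction is applied for
the temperature dependence of the crystallization enthalpy or for
differences between crystal forms — the free-fraction arithmetic is a
direct enthalpy ratio, and this is a documented limitation.

## Fraction decomposition

With drug mass fraction $w = 1 - f_{MS}$ and pure-drug references
$\Delta C_p^0$ and $\Delta H_{cc}^0$ (which must be supplied explicitly;
they are sample-specific and never assumed):

$$\mathrm{rigid} = 100\left(1 - \frac{\Delta C_p}{w\,\Delta C_p^0}\right),
\qquad
\mathrm{free} = 100\,\frac{\Delta H_{cc}}{w\,\Delta H_{cc}^0},
\qquad
\mathrm{intermediate} = 100 - \mathrm{rigid} - \mathrm{free}.$$

The raw triple sums to exactly 100 by construction; clipping to
$[0, 100]$ absorbs noise and the clipped triple is re-normalized only
when clipping pushed the sum above 100. Raw values are always retained
for diagnostics. `extrapolate_full_rigid_load()` fits the per-gram-of-
mixture $\Delta C_p$ against silica load by unweighted OLS and reports
the root; replicate scatter in such series is heteroscedastic and would
justify weighting, but weights are rarely available, so OLS is the
default and the choice is visible in the result object. A non-negative
slope (step not decreasing with load) is an error, not an extrapolation.

Note a geometric subtlety the synthetic tests exploit: a *linear* rigid
fraction versus load does **not** produce a linear $\Delta C_p$ line,
because the drug fraction $w$ shrinks simultaneously. Planting an
exactly straight line with root $r$ requires
$\mathrm{rigid}(f) = 100\,(1 - (1 - f/r)/(1 - f))$.

## Donth CRR sizing

$$L = \left[\frac{k_B T_g^2\,(1/C_{pg} - 1/C_{pl})}
{\rho\,(\delta T)^2}\right]^{1/3},$$

with $T_g$ the onset temperature (K), $\delta T$ half the onset-to-end
width, and the specific heats entering as $\Delta(1/c_p) > 0$ — the
standard Donth formulation. The ambient glass density is used because
the density at $T_g$ is rarely measured; the systematic error from
thermal expansion is at the percent level and enters as its cube root.
On celecoxib-like inputs (331 K, 2 K, 1410 kg/m³, 1620/2070 J/(kg K))
the formula gives 3.30 nm. Equal specific heats are degenerate and
return 0 with a warning rather than an error, so mapping over mixtures
does not abort.

## Dielectric relaxation

`fit_hn()` fits $\log_{10}\varepsilon''$ over the measured (log-spaced)
frequencies: the loss spans decades over a $10^9$ frequency range, and
fitting in log space weights all decades evenly. $\varepsilon'$ serves
as a cross-check by default (the Kramers–Kronig consistency of the
fitted $\Delta\varepsilon$ with the dispersion step is a test in the
suite); joint real+imaginary fitting is available behind the `fit_real`
flag. Initialization is automatic — $\tau$ from the loss-peak location,
$\Delta\varepsilon$ from twice the peak height, $a = 0.8$, $b = 0.6$,
$\sigma_{dc}$ from a low-frequency slope $-1$ segment when present — and
the fit is repeated from jittered starts ($\pm 0.5$ decade in $\tau$;
deterministic under the `seed` argument), keeping the best residual.
Two-process fits parametrise the second time constant as a non-negative
decade offset below the first, which structurally eliminates
label-switching. Whether the dc term is included is decided from the
data (`fit_sigma = "auto"`), and shape exponents are bounded in
$(0.05, 1]$.

The α-relaxation time is the reciprocal angular loss-peak frequency,
computed in closed form from the HN parameters; the suite verifies this
against a numerically located peak over random shapes to 1 %.

The VFT fit works on $\log_{10}\tau$, where scatter is approximately
homoscedastic. A grid scan over the Vogel temperature $T_0$ (each
candidate reducing to a linear problem) seeds a bounded
Levenberg–Marquardt refinement with $T_0$ constrained below the lowest
fitted temperature; Arrhenius-like data drive $T_0 \to 0$ with $D T_0$
converging to the activation temperature.

## KWW stretching exponent

The frequency-domain KWW loss is the one-sided Fourier transform of
$-\mathrm{d}\Phi/\mathrm{d}t$ with $\Phi = \exp(-(t/\tau)^\beta)$,
computed after integration by parts as
$\omega\int_0^\infty \cos(\omega t)\,\Phi(t)\,\mathrm{d}t$. The
oscillatory integral is evaluated by splitting the axis at the cosine
zeros, 16-point Gauss–Legendre quadrature per half-period lobe, and
Wynn epsilon-algorithm acceleration of the alternating partial sums;
this is uniformly accurate to about $10^{-10}$ over the $\beta$ and
$\omega\tau$ ranges used, confirmed against the Debye closed form at
$\beta = 1$ and against independently computed high-precision values at
$\beta = 1/2$. `fit_kww_beta()` fits the peak-normalized shape on the
log-frequency grid with an analytic amplitude, by box-constrained
quasi-Newton over $(\beta, \log_{10}\tau)$. Frequency-domain shape
fitting was chosen (rather than transforming the data to the time
domain) because normalized loss peaks are the form in which such data
are reported; the deconvolution of two-component spectra shares
$\varepsilon_\infty$ and $\sigma_{dc}$ across processes.

## Crystallization kinetics

Conversion comes from the normalized dielectric dispersion
$\varepsilon'_N = (\varepsilon'_0 - \varepsilon'_t)/(\varepsilon'_0 -
\varepsilon'_\infty)$ or from the residual $\Delta C_p$
($X = 1 - \Delta C_p(t)/\Delta C_p(0)$). `fit_avrami()` fits
$X(t) = 1 - \exp(-k (t-d)^n)$ by bounded Levenberg–Marquardt over
$(\log_{10} k, d, n)$ with $d \ge 0$, multi-started in $\log k$ and
seeded by the linearized double-log regression (which is only ever an
initializer — the nonlinear fit is authoritative). The terminal plateau
is estimated from the settled tail and, by default, conversions are
rescaled by it so the uncrystallized remainder is excluded from the
kinetics; free-plateau fitting is available behind a flag. $d$ is fitted
with a lower bound of 0 rather than fixed, since reported zero induction
times cannot be distinguished from small ones. $\varepsilon'_\infty$ is
never extrapolated from an unsettled tail — that is an error.

The rate constant is dimensionally $\mathrm{s}^{-n}$; because kinetic
tables in this field conventionally print $\mathrm{s}^{-1}$, the fit
object carries the same number under both labels (`k`, `k_per_s`), and
the discrepancy is deliberate and documented here.

**Identifiability.** $k$, $n$ and $d$ are strongly correlated: an error
$\delta n$ in the exponent displaces $\log_{10} k$ by roughly
$\delta n \cdot \log_{10} t_{1/2}$. At a 600 s sampling interval and
additive conversion noise of 0.01, the Cramér–Rao bound on
$\log_{10} k$ is about 0.2–0.3 decades for celecoxib-like kinetics with
$d$ free, and the package's maximum-likelihood fit attains that bound.
The robustly identified quantities are $n$ and the combined time scale
$t_{1/2} = d + (\ln 2 / k)^{1/n}$, which is recovered to a couple of
percent; tests and users should compare $t_{1/2}$, not raw $k$, across
conditions unless sampling is much denser than 600 s.

## Synthetic data and what passing tests show

Every generator (`gen_hn_spectrum`, `gen_vft_series`, `gen_thermogram`,
`gen_avrami_trace`, `gen_mixture_series`) emits a (data, truth, recipe)
triplet, is bit-reproducible under its seed, leaves the caller's RNG
stream untouched, and reduces exactly to the forward model at zero
noise. Defaults mirror the regime of interest: a 10⁻²–10⁷ Hz frequency
sweep, $T_g$ onset near 58 °C with $\Delta C_p \approx 0.45$ J/(g K),
$\beta$ between 0.55 and 0.69, crystallization with
$k \approx 10^{-7}\,\mathrm{s}^{-n}$, $n \approx 1.8$ and a 600 s
sampling cadence. Spectral noise is multiplicative by default
(instrument loss noise scales with signal), conversion and thermogram
noise additive.

The generators emulate the *functional forms* of real measurements —
HN-shaped peaks with dc conductivity, sigmoidal $C_p$ steps with
Gaussian thermal events on sloped baselines, Avrami-shaped conversions
with sub-unity plateaus — not instrument physics: there is no thermal
lag, no modulation deconvolution, no electrode polarization, no
secondary ($\beta/\gamma$) relaxations below $T_g$. Passing recovery
tests therefore demonstrates correctness and statistical efficiency of
the estimators under the stated noise models, not robustness to every
artifact of real instruments.

Problem sizes used by the test and acceptance suites: spectra of ~70
points (8 per decade over 9 decades), thermograms of ~700 points at
0.1 K steps, crystallization traces of 50–150 points, and 50-replicate
recovery studies per kinetic parameter set — small enough to run the
whole suite in well under a minute while leaving every estimator
over-determined.

## Known limitations

* The free-fraction enthalpy ratio ignores the temperature dependence of
  the crystallization enthalpy and crystal-form differences.
* The loading model's cubic footprint uses the bulk glass density; real
  adsorbed conformations differ, so monolayer numbers are estimates of
  scale.
* Pore size is treated as a single effective diameter; the distinction
  between mean and mode of a pore-size distribution is not modelled.
* `fit_kww_beta` assumes a single resolved peak; overlapping processes
  must be deconvolved with `fit_hn(n_processes = 2)` first.
* Melting-point depression in pores (Gibbs–Thomson) and diffraction-
  based polymorph identification are out of scope.
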