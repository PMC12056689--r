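Package: poreglass
Title: Dielectric and Calorimetric Analysis of Amorphous Drugs Confined in
    Mesoporous Silica
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for characterising the physical stability of amorphous
    (glassy) drugs mixed with mesoporous silica carriers. Implements
    Havriliak-Negami fitting of broadband dielectric loss spectra with dc
    conductivity, Vogel-Fulcher-Tammann temperature dependence of the alpha
    relaxation time, Kohlrausch-Williams-Watts stretching exponents from
    normalized loss peaks, tangent-construction glass-transition analysis of
    DSC thermograms, decomposition of the drug glass into rigid, intermediate
    and free fractions, Donth cooperatively-rearranging-region sizing,
    Avrami-Erofeev isothermal crystallization kinetics, and a geometric model
    of monolayer and pore-volume drug-loading capacity. Includes synthetic-data
    generators with known ground truth for every input class so the full
    pipeline is testable without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
Depends: R (>= 4.0)
Imports:
    minpack.lm,
    signal,
    stats,
    tools,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
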