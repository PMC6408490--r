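Package: chlorkin
Title: Chloride-Promoted Acid-Catalyzed Dehydration Kinetics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Batch-reactor kinetic analysis of acid-catalyzed sugar
    dehydration in polar aprotic solvent/water mixtures, with emphasis on
    the promotional effect of chloride ions. Provides nonlinear
    least-squares estimation of specific-acid rate constants with 95%
    confidence intervals from concentration-time profiles, a
    saturation-binding (Langmuir-form) transition-state model of the
    chloride rate enhancement fitted per solvent or globally with a shared
    enhancement factor, Arrhenius and kinetic-isotope-effect analysis,
    free-energy-profile bookkeeping, and a synthetic-data generator that
    emulates pseudo-first-order fructose decay, HMF formation with a
    selectivity branch, consecutive degradation to levulinic acid and
    multiplicative measurement noise.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    minpack.lm,
    stats,
    graphics,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
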