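Package: ironcline
Title: Fe(II) Fluxes and Photoferrotrophic Oxidation Rates in Stratified Lakes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Quantitative analysis chain for photoferrotrophic Fe(II)
    oxidation in ferruginous, permanently stratified (meromictic) lakes.
    Provides exact-rational stoichiometric algebra for redox reactions of
    anoxygenic iron-oxidizing photosynthesis and anaerobic organic-matter
    degradation, unit-aware depth-profile handling with linear gradient
    estimation across the chemocline, Fickian diffusive flux and
    layer-integrated volumetric Fe(II)-oxidation rates, carbon-uptake rates
    from 14C-bicarbonate tracer incubations with stoichiometric conversion
    to Fe(II)-oxidation rates, window and light-phase rate estimation from
    bottle-incubation time series with killed-control correction,
    photoferrotroph population-size estimation from cell-specific rates,
    and seeded synthetic-data generators with known ground truth for every
    pipeline stage.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
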