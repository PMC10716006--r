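Package: g6pflux
Title: Hepatic Glucose 6-Phosphate Flux Analysis from Triple-Tracer
    Mass Isotopomer Distributions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Steady-state analysis of in vivo hepatic carbohydrate fluxes
    from gas chromatography-mass spectrometry mass isotopomer
    distributions of blood glucose and urinary (UDP-)glucose measured
    under a triple stable-isotope tracer infusion ([U-13C]glucose,
    [2-13C]glycerol, [1-2H]galactose with paracetamol as a urinary
    UDP-glucose reporter). Provides natural-abundance correction of
    isotopologue spectra for the two glucose derivatization channels,
    mass isotopomer distribution analysis (MIDA) of gluconeogenic
    precursor enrichment, a glucose 6-phosphate flux-balance solver for
    glucokinase, glucose-6-phosphatase, glycogen synthase, glycogen
    phosphorylase and gluconeogenesis fluxes, a forward simulator of the
    infusion experiment for validation without animal data, and a
    factorial-design statistics stage (two-way ANOVA with Tukey
    post-hoc contrasts).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    readr,
    rlang,
    pracma,
    car,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
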