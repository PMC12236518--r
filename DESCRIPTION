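Package: stabscreen
Title: Small-Molecule Stabilization Screening by DSF, STD NMR and MMS
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Analysis of three-stage fragment screening campaigns for
    protein-stabilizing small molecules: differential scanning fluorimetry
    (DSF) melt-curve fitting and hit calling against a control, saturation
    transfer difference (STD) NMR amplification-factor buildup and Langmuir
    dissociation-constant estimation, and microfluidic modulation
    spectroscopy (MMS) amide-I similarity-spectrum deconvolution into
    secondary-structure fractions with per-structure melting temperatures
    and EC50 of thermal stabilization. Includes seeded synthetic-data
    generators with known ground truth for every stage.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    minpack.lm,
    signal,
    pracma,
    yaml,
    jsonlite,
    S4Vectors,
    SummarizedExperiment
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
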