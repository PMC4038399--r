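Package: holoscreen
Title: Template-Ligand Virtual Screening with Thermal-Shift Validation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Ligand homology modeling tools for virtual ligand screening:
    holo-template ranking by BLOSUM62 sum-of-pairs alignment scores, the
    weighted average-plus-maximum Tanimoto (mTC) compound score, combination
    of multiple evidence libraries by maximum score, and enrichment-factor /
    AUAC benchmarking with seeded random baselines. Also implements the
    downstream differential scanning fluorimetry (thermal shift) analysis
    used to validate screening hits: control subtraction, Boltzmann
    melt-curve fitting, Q-score curve triage, melting-temperature shifts,
    van't Hoff enthalpies and dissociation-constant estimates, plus seeded
    generators for synthetic screening libraries and 96-well melt plates.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.2)
Imports:
    ChemmineR,
    ChemmineOB,
    igraph,
    methods,
    minpack.lm,
    stats,
    utils,
    yaml
Suggests:
    Biostrings,
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
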