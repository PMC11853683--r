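Package: cristaflux
Title: Steady-State Reaction-Diffusion Modeling of ADP/ATP Handling in
    Mitochondrial Cristae
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: A "virtual mitochondrion" for studying how the topology of the
    mitochondrial inner membrane modulates ATP production. Solves the coupled
    steady-state reaction-diffusion system for external ADP/ATP fields
    (adenine nucleotide translocase on the membrane, F1F0-ATP synthase fed by
    a well-mixed matrix pool, and a surrogate kinase cycling ATP and ADP
    outside the matrix) inside parameterized 2-D and 3-D crista geometries
    with configurable crista-junction number, position and width, and crista
    branching. Provides the topology-analysis layer on top of the solver:
    intracristal ADP profiles and area-based depletion, the quadratic ADP
    gradient law, the Rule of 2, diffusion penalties, surface-area flux
    decomposition, speed-zone classification, flux-versus-length curves, and
    census-based whole-mitochondrion flux scoring, together with a synthetic
    crista-census generator emulating electron-tomography morphometrics of a
    cardiomyocyte mitochondrion.
License: MIT
Encoding: UTF-8
Imports:
    Matrix,
    methods,
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
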