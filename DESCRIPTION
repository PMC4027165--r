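Package: saxcraft
Title: Small-Angle X-Ray Scattering Analysis of Protein Assemblies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A desk-scale small-angle X-ray scattering (SAXS) inference
    chain for protein assemblies in solution: Debye-formula forward
    scattering from atomic or bead models, primary curve reduction
    (Guinier fit, Porod invariants, regularized indirect Fourier
    transform for p(r) and Dmax, volume-of-correlation molecular
    weights), non-negative mixture-fraction fitting of conformer
    ensembles, chi-square scoring and ranking of candidate poses and
    assembly stoichiometries, simplified ab initio bead-model
    reconstruction by simulated annealing, and time-resolved Guinier
    and two-state kinetic analysis of stopped-flow series.  A synthetic
    toy-assembly generator emulating open/closed GTPase homodimers and
    their higher-order complexes supplies every input the pipeline
    needs, so the whole package builds and tests offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    bio3d,
    pracma,
    minpack.lm
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    knitr
Config/testthat/edition: 3
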