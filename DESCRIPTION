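Package: smstoich
Title: Single-Molecule Brightness Stoichiometry for Membrane Protein Oligomers
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for inferring the subunit stoichiometry of membrane protein
    oligomers from single-molecule TIRF microscopy. Provides a synthetic movie
    generator with an EMCCD camera noise model and ground-truth tables,
    difference-of-Gaussians spot detection with 2D Gaussian photometry and
    local background subtraction, calibrated Gaussian-mixture decomposition of
    brightness distributions into oligomer occurrence fractions with binomial
    correction for partial fluorophore labeling, nearest-neighbour track
    linking with mobile/immobile classification, particle-density
    quantification, and the calcein-release statistic for liposome leakage
    assays.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    pracma,
    tiff,
    yaml,
    jsonlite,
    minpack.lm,
    mclust,
    EBImage,
    withr
Suggests:
    testthat (>= 3.0.0),
    knitr,
    rmarkdown,
    optparse
VignetteBuilder: knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
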