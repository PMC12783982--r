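Package: odourpop
Title: Single-Unit and Population Analysis of Odour-Evoked Spiking
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for odour-evoked spiking activity recorded in
    the olfactory bulb and anterior olfactory nucleus: z-scored PSTH response
    classification, response-feature extraction, pairwise discriminability
    (d-prime), chemical-similarity coding curves with two-way ANOVAs and
    Sidak post-hocs, cross-odour population-vector Euclidean distances with
    Welch/Brown-Forsythe ANOVA and Games-Howell post-hocs, and a subsampled
    PCA plus Gaussian-model leave-one-trial-out odour decoder with a kNN/ECOC
    control classifier. Includes an inhomogeneous-Poisson spike-train
    generator emulating the experimental design (six aldehydes of carbon
    chain length 3-8, 19 trials each, 500 ms stimulation) with genotype
    presets, plus spike-detection preprocessing (common average referencing,
    Butterworth band-pass, median-based amplitude thresholding) for synthetic
    raw traces.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    signal,
    car
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
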