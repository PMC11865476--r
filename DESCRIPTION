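Package: replistage
Title: Spatiotemporal Staging of DNA Replication from Fluorescence Images of Nuclei
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies DNA-replication spatiotemporal dynamics from
    multi-channel fluorescence images of nuclei. Provides DAPI-based nucleus
    segmentation (Otsu thresholding and seeded watershed), a transparent
    per-criterion quality-control filter engine with mESC and U2OS threshold
    dialects, a supervised S-phase stage classifier trained with weighted
    resampling and cosine-annealing warm restarts, a from-scratch BYOL
    self-supervised embedder, common-PC-space projection with kernel-density
    maps and threshold-proportion statistics (two-proportion Z-tests,
    chi-squared homogeneity, normal-approximation confidence intervals), and
    a seeded synthetic-microscopy generator that renders the five S-phase
    replication-foci pattern classes, EdU-negative G1/G2 nuclei and imaging
    artifacts so the full pipeline is exercisable at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    MASS,
    stats,
    utils,
    grDevices,
    graphics,
    tools,
    tiff,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
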