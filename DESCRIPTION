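Package: hypernuc
Title: Archaeal Hypernucleosome Chromatin, Single-Molecule and Structure Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantitative analysis of archaeal histone-based chromatin built
    around tetramer-forming histone variants. Provides MNase-seq
    chromatin-particle analysis (fragment-size spectra, ladder periodicity,
    particle size classes, mid-point frequency tracks, TSS-anchored occupancy
    maps, and a 60-bp-multiple versus odd-30-bp-multiple log2 coverage-bias
    statistic over 120-bp bins), tethered-particle-motion (TPM)
    compaction-step analysis (RMS displacement, Gaussian-mixture population
    deconvolution, extreme-position end-to-end estimation, skew-normal fits
    and pairwise step spectra), DNA-bridging recovery quantification with
    Hill-curve midpoint estimation, and distance geometry on atomic models
    (inter-chain C-alpha distances, disulfide-compatibility windows,
    salt-bridge detection). Seeded synthetic-data generators emulate the
    statistical structure of each assay so that every stage is testable
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    IRanges,
    S4Vectors,
    GenomicRanges,
    rtracklayer,
    Rsamtools,
    mclust,
    minpack.lm,
    bio3d,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
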