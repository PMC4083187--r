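Package: mscomet
Title: Methylation-Sensitive Comet Assay Simulation and Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for estimating global CpG methylation from
    methylation-sensitive comet assay data. Per-cell tail-intensity
    measurements from HpaII-, MspI- and mock-digested nucleoids are combined
    into a percentage-methylation statistic with modified Thompson tau
    outlier rejection and percentile-bootstrap confidence intervals. The
    package also simulates per-cell comet populations and synthetic comet
    images with known ground truth, scores comet images into tail-intensity
    percentages, and implements the companion cytosine extension assay (CEA)
    calculation from scintillation counts.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    EBImage,
    tiff,
    yaml,
    optparse
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
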