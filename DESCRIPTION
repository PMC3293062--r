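Package: texclust
Title: Texture Analysis and Neural-Network Clustering of Histology Micrographs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies tissue morphology in histology micrographs with
    classical texture statistics (gray-level co-occurrence, run-length and
    gradient features), ranks the descriptors by Fisher coefficient, groups
    samples by unsupervised winner-take-all neural-network clustering, and
    characterizes the resulting clusters with group-distribution tables and
    weighted-average descriptor profiles. Includes seeded synthetic-data
    generators for two-class tubular-tissue texture images with a continuous
    degeneration parameter and for per-animal indicator tables drawn from
    published group summary statistics, so the whole pipeline is testable
    without access to the original micrographs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    grDevices,
    graphics,
    jsonlite,
    png,
    stats,
    tools,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
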