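Package: refstab
Title: Reference Gene Selection and Expression Stability Analysis for qRT-PCR
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Tools for identifying and validating qRT-PCR reference
    (housekeeping) genes. Screens RNA-seq FPKM matrices for stably
    expressed candidates (mean, standard deviation, coefficient of
    variation and maximum fold change filters), fits dilution-series
    standard curves and derives amplification efficiencies, scores
    candidate stability with four independent statistics (comparative
    delta-Ct, BestKeeper, geNorm with iterative exclusion and pairwise
    variation, and the model-based NormFinder variance decomposition),
    combines them into a RefFinder-style geometric-mean consensus
    ranking, and quantifies target genes against one or several
    reference genes with the 2^-ddCt method. A seeded simulator
    generates Ct and FPKM data with known ground truth for
    benchmarking every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    tools,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
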