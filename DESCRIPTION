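Package: omniflux
Title: Multi-Omics Resource Allocation Analysis for Recombinant-Protein-Producing Yeast
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Spike-in-calibrated absolute quantification of transcriptomes (FPKM +
    external mRNA standards) and proteomes (iBAQ + UPS2-style dynamic-range
    standards, propagated through TMT ratios), allocation of the absolute layers
    to biological-process gene sets as mole and mass fractions with differential
    testing, protein-mRNA correlation and translation propensity, steady-state
    chemostat rate arithmetic, and enzyme-constrained flux balance analysis with
    a non-growth-associated maintenance (NGAM) objective on a toy GECKO-style
    network. Ships a synthetic-data generator with recorded ground truth so the
    whole pipeline is testable end to end without any external download.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
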