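Package: porineva
Title: Entropy-Variability Analysis of Bacterial Beta-Barrel Porins
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Structure-and-sequence analysis of bacterial outer-membrane
    porins and specific diffusion channels. Reads and cleans protein
    structures, partitions beta-barrel topology (strands, periplasmic
    turns, extracellular loops) from a Kabsch-Sander style hydrogen-bond
    assignment, extracts barrel cores, superposes cores with iterative
    outlier trimming, profiles minimum pore radii along the barrel axis,
    filters multiple sequence alignments for redundancy and divergence,
    computes per-column Shannon entropy and variability with a five-box
    functional classification, and maps conservation boxes onto
    structural regions. Includes generators for idealized barrels and
    alignments with known ground truth, and a pipeline orchestrator.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    bio3d,
    Biostrings,
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
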