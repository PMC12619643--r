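Package: paeseg
Title: Schema-Free Protein Domain Segmentation from AlphaFold Predicted
    Aligned Error
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Segments predicted protein structures into domains using only
    AlphaFold's Predicted Aligned Error (PAE) matrix. Residues become nodes
    of a fully connected graph whose edge weights are a logistic transform
    of the PAE values around a tuneable contrast threshold; Leiden community
    detection under a tuneable resolution parameter yields clusters that are
    mapped back to (possibly discontinuous) residue intervals. Includes
    readers for the PAE JSON dialects in circulation and for PDB/mmCIF
    structures, CATH-style domain chopping serialization, intersection-over-
    union evaluation against reference annotations, a synthetic PAE
    generator with planted domain structure for testing, PAE heatmap
    plotting with domain overlays, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    bio3d,
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
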