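Package: protscales
Title: Amino-Acid Descriptor Scales for Proteochemometric and Peptide QSAR Modeling
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Encodes protein and peptide sequences into thirteen published
    amino-acid descriptor sets (Z-scales, VHSE, T-scales, ST-scales, MS-WHIM,
    FASGAI, BLOSUM-derived indices and the ProtFP family), derives ProtFP-style
    descriptors from raw amino-acid property matrices (AAindex1 parsing,
    unit-interval scaling, recursive elimination of co-varying indices,
    principal component analysis), and quantifies how similarly descriptor sets
    perceive amino-acid space via scaled 20x20 Euclidean distance matrices,
    pairwise distance-difference statistics and an inter-descriptor PCA.
    Tibble-first interfaces with broom-style tidy()/glance() methods and
    ggplot2 visualisations.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    generics,
    ggplot2,
    stats,
    utils,
    tools
Suggests:
    Biostrings,
    testthat (>= 3.0.0),
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
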