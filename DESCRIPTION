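Package: diauxielfq
Title: Label-Free Quantitative Proteomics of the Glucose-Lactose Diauxic Shift
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested, reusable pipeline for label-free LC-MS protein
    quantitation across a bacterial diauxic shift: identification score
    filtering and target-decoy FDR estimation, retention-time alignment of
    runs onto a master time base via identified-peptide anchors, windowed
    extracted-ion intensity assembly into a peptide-by-sample matrix,
    unique-peptide protein rollup, reference-protein and earliest-time-point
    normalization with log2 ratios, growth-curve onset detection and
    replicate time alignment, CLARA-style k-medoids clustering of expression
    profiles, protein-mRNA lag estimation, and KEGG pathway color export.
    Includes a synthetic-data generator that emulates the glucose-lactose
    diauxie experiment (growth curves, tryptic peptides, per-run feature
    maps with monotone retention-time distortion, identification lists with
    decoys) so every stage is testable against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    cluster,
    dplyr,
    generics,
    ggplot2,
    pracma,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    Biostrings,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
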