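Package: ampholyte
Title: Isoelectric Point Estimation for Peptides and Proteins
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates the isoelectric point (pI) of peptide and protein
    sequences from Henderson-Hasselbalch net-charge models over interchangeable
    published pKa basis sets. Implements five algorithm families (iterative
    bisection, position-dependent Bjellqvist terminal variants, sequence-context
    Cofactor and Branca corrections, and a retrainable support-vector
    regression), models the charge effects of phosphorylation and N-terminal
    acetylation, and provides a benchmarking layer (Pearson correlation, RMSD,
    outlier flagging, per-fraction summaries) together with seeded synthetic
    generators emulating OFF-GEL fractionated peptide experiments and
    multi-measurement protein pI tables.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    readr,
    stringr,
    ggplot2,
    generics,
    e1071,
    seqinr,
    withr,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
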