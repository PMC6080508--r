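Package: homoeologr
Title: Homoeolog Expression Bias and Expression Level Dominance in
    Allopolyploids
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis of duplicate-gene expression in a resynthesized
    allopolyploid relative to its two diploid parents. Implements
    differential-expression calling between each subgenome and its parent,
    per-pair homoeolog expression bias with parental-to-progeny transitions,
    the twelve-category expression-level-dominance (ELD) decision table with
    transgressive and additive classes, the homoeolog-level decomposition
    that explains ELD, hypergeometric term enrichment, and window-based
    coverage-depth ratios for chromosome-integrity checks. A synthetic-data
    generator with exact-mean ground-truth labels makes every stage testable
    without sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
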