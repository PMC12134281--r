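Package: endodiv
Title: Diversity and Bioassay Analytics for Culture-Based Endophyte Surveys
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing culture-based surveys of endophytic fungi and
    the bioprospecting assays that usually accompany them. Computes occurrence
    and colonization-frequency percentages, alpha-diversity indices (Shannon,
    Simpson complement, Camargo 1/S, Berger-Parker) with per-index rounding
    conventions, tissue-overlap sets and a genus-by-tissue ordination;
    reconstructs integer abundance vectors consistent with published rounded
    index values by exhaustive enumeration; and analyses bioassay tables:
    DPPH radical-scavenging percentages, inhibition-zone summaries with
    one-way ANOVA and Duncan's multiple range test, four-parameter logistic
    dose-response fits with IC50/CC50 and the selectivity index. Seeded
    generators simulate community tables, dose-response plates and DPPH
    absorbance pairs so every stage is testable without external data.
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
    minpack.lm,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    vegan
Config/testthat/edition: 3
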