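Package: copediv
Title: Clone-Library Diversity and Copepod Development Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for 16S rRNA clone-library surveys of
    crustacean-associated bacterial communities and their link to host
    development. Bins clone sequences into phylotypes at a 97% identity
    threshold, computes Brillouin diversity and relative evenness for
    censored communities, scores copepod development endpoints
    (survivorship, percent copepodites, development index), and runs the
    small-sample statistical layer (Box-Cox transformation, pooled-variance
    t-tests, one-way ANOVA with Tukey HSD, Spearman rank correlation with
    exact permutation p-values). A synthetic-data generator produces
    reference ribotypes, error-bearing clone libraries and replicate stage
    censuses so the whole pipeline is testable without sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    MASS,
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
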