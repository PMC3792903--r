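Package: famclust
Title: Familial Clustering of Cause-Specific Mortality on Population Genealogies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for detecting familial clustering of cause-specific
    mortality in genealogy-linked death records. Implements Malecot kinship
    coefficients on arbitrary pedigree graphs, the Genealogical Index of
    Familiality (GIF) and its distant variant with matched-control empirical
    significance, cohort-standardized observed/expected relative risks of
    death among first-, second- and third-degree relatives of cases, and a
    founder-descendancy scan for pedigrees with a significant excess of
    disease deaths. A seeded generator of multi-generation genealogies with
    linked synthetic death certificates provides a complete test bed, so the
    full pipeline runs without access to restricted population databases.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    stats,
    utils,
    jsonlite,
    generics,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    readr,
    withr,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
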