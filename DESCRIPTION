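Package: covolatilome
Title: Source Apportionment and Analysis of Microbial Co-Culture Volatilomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing PTR-ToF-MS volatilome peak tables from
    fungal-bacterial co-cultivation experiments. Provides blank and
    autocorrelation filtering of mass peaks, growth-medium (PDA)
    null-distribution background correction yielding signed
    production/consumption values, binomial models of consumption
    probability across detection thresholds, linear source-apportionment
    models that decompose co-culture volatile concentrations into scaled
    bacterial and fungal pure-culture contributions, residual-based
    discovery of potentially regulated volatiles, linear discriminant
    prediction of taxonomy and cultivation mode, nested analysis of
    variance of fungal radial growth rates, retention-index computation,
    and a ground-truthed synthetic experiment generator for validating
    every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    MASS,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
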