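# Bundled reference tables from a published 25-strain Mortierellaceae x
# Pseudomonas co-cultivation study, as printed: the per-strain
# decomposition coefficients of models 1-3 and the growth-rate ANOVA
# sums of squares.  Useful as desk-scale inputs for the cross-model
# correlation and effect-size computations.

#' Published per-strain decomposition coefficients
#'
#' Model-1 fungal and bacterial coefficients (with SE and significance),
#' model-2 bacterial and model-3 fungal coefficients, adjusted R-squared
#' and the number of VOCs per model, for 25 fungal strains co-cultivated
#' with a VOC-producing pseudomonad.  Significance codes: `**` p < 0.001,
#' `*` p < 0.05, `ns` not significant.
#'
#' @return A tibble, one row per strain.
#' @export
published_coefficients <- function() {
  readr::read_csv(system.file("extdata", "coculture_model_coefficients.csv",
                              package = "covolatilome"),
                  show_col_types = FALSE, progress = FALSE)
}

#' Published growth-ANOVA sums of squares
#'
#' Degrees of freedom and sequential sums of squares of the nested
#' growth-rate ANOVA (species, medium, cultivation mode, strain nested in
#' species, and their interactions, plus residuals) from the same study.
#'
#' @return A tibble with columns `term`, `df`, `sumsq`.
#' @export
published_growth_sumsq <- function() {
  readr::read_csv(system.file("extdata", "growth_anova_sumsq.csv",
                              package = "covolatilome"),
                  show_col_types = FALSE, progress = FALSE)
}
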