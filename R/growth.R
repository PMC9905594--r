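# Nested ANOVA of fungal daily radial growth rates, per-strain pure-vs-co
# comparisons, and the proof-of-concept correlations linking growth,
# decomposition coefficients, and discriminant centroid distances.

growth_cols <- c("strain", "species", "medium", "mode", "replicate", "rate")

validate_growth <- function(records) {
  missing <- setdiff(growth_cols, names(records))
  if (length(missing)) {
    abort(paste0("Growth records lack column(s): ",
                 paste(missing, collapse = ", ")))
  }
  if (any(records$rate < 0)) abort("Growth rates must be non-negative.")
  key <- paste(records$strain, records$medium, records$mode,
               records$replicate)
  if (anyDuplicated(key)) {
    abort(paste0("Duplicate growth record: ", key[anyDuplicated(key)][1]))
  }
  invisible(records)
}

# Sequential (type-I) ANOVA terms, in the reporting order of the nested
# growth model: main effects, strain nested in species, then interactions.
# Labels are in R's canonical variable order (species, medium, mode, strain)
# so they match aov()'s term names exactly.
growth_terms <- c("species", "medium", "mode", "species:strain",
                  "species:medium", "species:mode",
                  "species:medium:strain", "species:mode:strain")

#' Nested ANOVA of daily radial growth rates
#'
#' Fits the full fixed-effects model of rate on species, medium,
#' cultivation mode, strain nested within species, and their interactions,
#' using sequential (type-I) sums of squares in that order.  The model is
#' then reduced: starting from the highest-order interactions, terms
#' insignificant at `alpha` are dropped (a main effect contained in a kept
#' interaction is never dropped) until all remaining terms are significant.
#' Effect sizes are the percentage of the total sum of squares (residual
#' included) explained by each term.
#'
#' @param records Growth-record tibble with columns `strain`, `species`,
#'   `medium`, `mode`, `replicate`, `rate`.
#' @param alpha Significance level for the model reduction.
#' @param reduce Perform the term reduction (default) or keep the full
#'   model.
#' @return A tibble of class `anova_table`: `term`, `df`, `sumsq`,
#'   `meansq`, `statistic`, `p_value`, `effect_pct`, with attributes
#'   `overall` (F, df, p, adjusted R-squared) and `degenerate`.
#' @export
fit_growth_anova <- function(records, alpha = 0.05, reduce = TRUE) {
  validate_growth(records)
  cells <- records %>%
    distinct(.data$species, .data$medium, .data$mode)
  expected <- tidyr::expand_grid(species = unique(records$species),
                                 medium = unique(records$medium),
                                 mode = unique(records$mode))
  empty <- dplyr::anti_join(expected, cells,
                            by = c("species", "medium", "mode"))
  if (nrow(empty)) {
    abort(paste0("Empty design cell(s): ",
                 paste(paste(empty$species, empty$medium, empty$mode,
                             sep = "/"), collapse = ", ")))
  }
  dat <- mutate(records,
                species = factor(.data$species), strain = factor(.data$strain),
                medium = factor(.data$medium), mode = factor(.data$mode))
  degenerate <- var(dat$rate) == 0

  fit_terms <- function(terms) {
    fml <- stats::reformulate(terms, response = "rate")
    fit <- aov(fml, data = dat)
    tab <- summary(fit)[[1]]
    tibble(term = trimws(rownames(tab)), df = tab$Df, sumsq = tab$`Sum Sq`,
           meansq = tab$`Mean Sq`, statistic = tab$`F value`,
           p_value = tab$`Pr(>F)`)
  }
  terms <- growth_terms
  # drop terms absent from the design (e.g. a single medium)
  terms <- terms[vapply(terms, function(tm) {
    all(vapply(strsplit(tm, ":")[[1]],
               function(v) length(unique(dat[[v]])) > 1, logical(1)))
  }, logical(1))]
  tab <- fit_terms(terms)
  if (reduce && !degenerate) {
    repeat {
      rows <- tab[tab$term != "Residuals", , drop = FALSE]
      # protected: terms contained in a retained higher-order term
      contained <- function(tm) {
        any(vapply(setdiff(rows$term, tm), function(other) {
          all(strsplit(tm, ":")[[1]] %in% strsplit(other, ":")[[1]])
        }, logical(1)))
      }
      order_of <- lengths(strsplit(rows$term, ":"))
      droppable <- !is.na(rows$p_value) & rows$p_value >= alpha &
        !vapply(rows$term, contained, logical(1))
      if (!any(droppable)) break
      victim <- rows$term[droppable][which.max(order_of[droppable])]
      # match by variable set: aov may canonicalize interaction labels
      vvars <- strsplit(victim, ":")[[1]]
      keep <- !vapply(terms, function(tm)
        setequal(strsplit(tm, ":")[[1]], vvars), logical(1))
      if (all(keep)) break  # should not happen; guard against stalling
      terms <- terms[keep]
      if (!length(terms)) break
      tab <- fit_terms(terms)
    }
  }
  total <- sum(tab$sumsq)
  tab$effect_pct <- if (total > 0) 100 * tab$sumsq / total else NA_real_
  resid_row <- tab$term == "Residuals"
  model_ss <- sum(tab$sumsq[!resid_row])
  model_df <- sum(tab$df[!resid_row])
  resid_df <- tab$df[resid_row]
  overall_f <- if (degenerate || !model_df) NA_real_ else
    (model_ss / model_df) / (tab$sumsq[resid_row] / resid_df)
  n <- nrow(dat)
  r2 <- if (total > 0) model_ss / total else NA_real_
  structure(tab,
            overall = list(f = overall_f, df1 = model_df, df2 = resid_df,
                           p = if (is.na(overall_f)) NA_real_ else
                             pf(overall_f, model_df, resid_df,
                                lower.tail = FALSE),
                           adj_r2 = if (is.na(r2)) NA_real_ else
                             1 - (1 - r2) * (n - 1) / (n - model_df - 1)),
            degenerate = degenerate,
            class = c("anova_table", class(tab)))
}

#' Effect sizes from sums of squares
#'
#' Computes the percentage of the total sum of squares (residual included)
#' explained by each factor.
#'
#' @param sumsq Named non-negative numeric vector of per-factor sums of
#'   squares, including the residual.
#' @param digits Optional rounding of the percentages.
#' @return A tibble: `term`, `sumsq`, `effect_pct`.
#' @export
effect_sizes <- function(sumsq, digits = NULL) {
  stopifnot(is.numeric(sumsq), all(sumsq >= 0))
  total <- sum(sumsq)
  if (total <= 0) abort("Total sum of squares must be positive.")
  pct <- 100 * sumsq / total
  if (!is.null(digits)) pct <- round(pct, digits)
  tibble(term = if (is.null(names(sumsq)))
           paste0("term", seq_along(sumsq)) else names(sumsq),
         sumsq = unname(sumsq), effect_pct = unname(pct))
}

#' Per-strain comparison of pure and co-culture growth rates
#'
#' For each strain x medium, a Welch two-sample test of pure versus
#' co-culture rates.  The direction is `faster`/`slower` (co-culture vs
#' pure) when significant at `alpha`, `ns` otherwise.  No multiplicity
#' correction is applied.
#'
#' @param records Growth-record tibble.
#' @param alpha Significance level.
#' @return A tibble: `strain`, `medium`, `mean_pure`, `mean_co`,
#'   `difference` (co - pure, mm/day), `p_value`, `direction`.
#' @export
compare_growth <- function(records, alpha = 0.05) {
  validate_growth(records)
  out <- list()
  for (key in split(records,
                    paste(records$strain, records$medium, sep = "\r"))) {
    pure <- key$rate[key$mode == "pure"]
    co <- key$rate[key$mode == "co"]
    if (length(pure) < 2 || length(co) < 2) {
      warn(paste0("Strain ", key$strain[1], " on ", key$medium[1],
                  " lacks replicated rates for a mode; skipped."))
      next
    }
    p <- welch_p(co, pure)
    diff <- mean(co) - mean(pure)
    out[[length(out) + 1]] <- tibble(
      strain = key$strain[1], medium = key$medium[1],
      mean_pure = mean(pure), mean_co = mean(co), difference = diff,
      p_value = p,
      direction = if (is.na(p) || p >= alpha) "ns"
                  else if (diff > 0) "faster" else "slower")
  }
  arrange(bind_rows(out), .data$strain, .data$medium)
}

#' Correlate decomposition coefficients with growth and centroid distances
#'
#' Joins, per strain, the bacterial and fungal decomposition coefficients,
#' the discriminant centroid distance between pure and co-culture, and the
#' growth-rate difference (co - pure).  Each coefficient is correlated
#' (Pearson and Spearman) with the centroid distance and with the growth
#' difference under two scenarios: `raw` mean differences, and `zeroed`
#' where differences insignificant at `alpha` are set to zero.
#'
#' @param comparisons Output of [compare_growth()] (one medium).
#' @param fits List of `decomposition_fit` objects.
#' @param distances Output of [centroid_distances()].
#' @param medium Which medium's growth comparisons to use.
#' @return A tibble: `coefficient`, `model`, `target`, `scenario`,
#'   `method`, `r`, `p_value`, `n`.
#' @export
correlate_with_volatilome <- function(comparisons, fits, distances,
                                      medium = "PDA") {
  tab <- decomposition_table(fits)
  tab <- tab[!is.na(tab$term), , drop = FALSE]
  comp <- comparisons[comparisons$medium == medium, , drop = FALSE]
  comp$zeroed <- ifelse(comp$direction == "ns", 0, comp$difference)
  out <- list()
  for (row in split(distinct(tab, .data$model, .data$term),
                    seq_len(nrow(distinct(tab, .data$model, .data$term))))) {
    coefs <- tab[tab$model == row$model & tab$term == row$term, ]
    merged <- coefs %>%
      left_join(distances, by = "strain") %>%
      left_join(comp, by = "strain")
    targets <- list(centroid_distance = merged$distance,
                    growth_difference_raw = merged$difference,
                    growth_difference_zeroed = merged$zeroed)
    for (tg in names(targets)) {
      ok <- stats::complete.cases(merged$estimate, targets[[tg]])
      if (sum(ok) < 4) {
        abort("Fewer than 4 matched strains for a correlation.")
      }
      for (m in c("pearson", "spearman")) {
        ct <- suppressWarnings(cor.test(merged$estimate[ok],
                                        targets[[tg]][ok], method = m))
        out[[length(out) + 1]] <- tibble(
          coefficient = ifelse(row$term == "B", "bacterial", "fungal"),
          model = row$model,
          target = sub("_raw$|_zeroed$", "", tg),
          scenario = if (grepl("zeroed", tg)) "zeroed"
                     else if (grepl("raw", tg)) "raw" else "none",
          method = m, r = unname(ct$estimate), p_value = ct$p.value,
          n = sum(ok))
      }
    }
  }
  bind_rows(out)
}
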