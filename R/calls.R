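# Production/consumption calling, strong-effect flags, binomial consumption
# models across detection thresholds, and the bacterial-vs-fungal paired
# comparison of concentration levels.

#' Group label for each culture row
#' @keywords internal
culture_group <- function(data) {
  case_when(
    data$role == "bacterial_pure" ~ "bacterium",
    data$role == "fungal_pure" ~ paste0(data$strain, ":pure"),
    data$role == "co_culture" ~ paste0(data$strain, ":co"),
    TRUE ~ NA_character_)
}

#' Call production and consumption per group and peak
#'
#' Group means of corrected concentrations are thresholded; positive means
#' are called `produced`, negative `consumed`, zero `background`.  A call is
#' flagged `strong` when the group mean magnitude exceeds
#' `(strong_fold - 1)` times the medium (PDA) mean for peaks the medium
#' emits (i.e. more than `strong_fold`-fold above/below the medium level);
#' peaks undetected in the medium have no fold reference, so any nonzero
#' call counts as strong there.
#'
#' @param corrected A corrected volatilome tibble.
#' @param pda_mean Named numeric vector of per-peak medium means (see
#'   [pda_means()]).
#' @param threshold Detection limit (ppbV) applied to group-mean magnitudes.
#' @param strong_fold Fold-change bound for the strong flag.
#' @return A tibble with one row per (group, peak): `group`, `role`,
#'   `species`, `strain`, `mode`, `peak`, `mean_conc`, `call`, `strong`,
#'   `threshold`.
#' @export
call_production <- function(corrected, pda_mean, threshold = 0.2,
                            strong_fold = 2) {
  validate_volatilome(corrected)
  if (!is_corrected(corrected)) {
    abort("call_production() needs a background-corrected matrix.")
  }
  peaks <- peak_labels(corrected)
  missing <- setdiff(peaks, names(pda_mean))
  if (length(missing)) {
    abort(paste0("pda_mean missing for peak(s): ",
                 paste(head(missing, 3), collapse = ", ")))
  }
  data <- corrected
  data$group <- culture_group(data)
  data <- data[!is.na(data$group), , drop = FALSE]
  long <- tidyr::pivot_longer(
    data[, c("group", "role", "species", "strain", peaks)],
    cols = all_of(peaks), names_to = "peak", values_to = "conc")
  calls <- long %>%
    group_by(.data$group, .data$role, .data$species, .data$strain,
             .data$peak) %>%
    summarise(mean_conc = mean(.data$conc), .groups = "drop")
  calls$mean_conc[abs(calls$mean_conc) < threshold] <- 0
  pda <- unname(pda_mean[calls$peak])
  pda_detected <- pda >= max(threshold, .Machine$double.eps)
  calls %>%
    mutate(
      mode = case_when(.data$role == "bacterial_pure" ~ "pure",
                       .data$role == "fungal_pure" ~ "pure",
                       .data$role == "co_culture" ~ "co"),
      call = case_when(.data$mean_conc > 0 ~ "produced",
                       .data$mean_conc < 0 ~ "consumed",
                       TRUE ~ "background"),
      strong = ifelse(pda_detected,
                      abs(.data$mean_conc) > (strong_fold - 1) * pda,
                      .data$call != "background"),
      threshold = threshold) %>%
    select("group", "role", "species", "strain", "mode", "peak",
           "mean_conc", "call", "strong", "threshold")
}

#' Model the probability of consumption across detection thresholds
#'
#' For each threshold, fits a binomial GLM with logit link of the outcome
#' consumed (1) versus produced (0) -- background calls excluded by default
#' -- on the taxon of the pure culture, with the bacterium as reference
#' level, so taxon coefficients are fungal-vs-bacterial log-odds differences
#' of consumption.  Taxa with no informative calls are dropped with a
#' warning; complete separation is flagged.
#'
#' @param calls A calls tibble from [call_production()], or several bound
#'   together with a `threshold` column covering the scan.
#' @param taxon Predictor granularity: `"species"` or `"strain"`.
#' @param include_background Treat background calls as non-consumption
#'   instead of excluding them.
#' @return A list of class `consumption_models` with `coefficients`
#'   (tibble: threshold, term, estimate, std_error, p_value, separation)
#'   and `comparison` (per threshold, the mean fungal-vs-bacterial
#'   log-odds difference).
#' @export
fit_consumption_models <- function(calls, taxon = c("species", "strain"),
                                   include_background = FALSE) {
  taxon <- arg_match(taxon)
  pure <- calls[calls$mode == "pure", , drop = FALSE]
  pure$taxon <- ifelse(pure$role == "bacterial_pure", "bacterium",
                       pure[[taxon]])
  if (length(unique(pure$taxon)) < 2) abort("Need at least two taxa.")
  if (!include_background) {
    pure <- pure[pure$call != "background", , drop = FALSE]
  }
  pure$outcome <- as.integer(pure$call == "consumed")
  res <- lapply(sort(unique(pure$threshold)), function(th) {
    dat <- pure[pure$threshold == th, , drop = FALSE]
    empty <- setdiff(unique(calls[[taxon]]), unique(dat$taxon))
    empty <- empty[!is.na(empty)]
    if (length(empty)) {
      warn(paste0("Taxa without informative calls at threshold ", th,
                  ": ", paste(empty, collapse = ", ")))
    }
    dat$taxon <- stats::relevel(factor(dat$taxon), ref = "bacterium")
    fit <- suppressWarnings(stats::glm(outcome ~ taxon, binomial(), dat))
    separated <- !fit$converged || any(abs(coef(fit)) > 15, na.rm = TRUE)
    cf <- summary(fit)$coefficients
    tibble(threshold = th, term = rownames(cf),
           estimate = cf[, "Estimate"], std_error = cf[, "Std. Error"],
           p_value = cf[, "Pr(>|z|)"], separation = separated)
  })
  coefs <- bind_rows(res)
  comparison <- coefs %>%
    filter(.data$term != "(Intercept)") %>%
    group_by(.data$threshold) %>%
    summarise(mean_log_odds_diff = mean(.data$estimate),
              all_positive = all(.data$estimate > 0), .groups = "drop")
  structure(list(coefficients = coefs, comparison = comparison,
                 taxon = taxon),
            class = "consumption_models")
}

#' Compare bacterial and mean fungal concentration levels
#'
#' Pairs, per peak, the bacterial pure-culture mean with the mean across all
#' fungal pure-culture strains and runs a paired t-test.  A positive mean
#' difference says the bacterium emits at higher concentrations than the
#' average fungus.
#'
#' @param corrected A corrected volatilome tibble with bacterial and fungal
#'   pure-culture rows.
#' @return A one-row tibble: `mean_difference`, `statistic`, `df`,
#'   `p_value`, `n_peaks`.
#' @export
compare_bacterial_vs_fungal_levels <- function(corrected) {
  validate_volatilome(corrected)
  peaks <- peak_labels(corrected)
  bact <- corrected[corrected$role == "bacterial_pure", peaks, drop = FALSE]
  fung <- corrected[corrected$role == "fungal_pure", , drop = FALSE]
  if (nrow(bact) == 0 || nrow(fung) == 0) {
    abort("Need bacterial and fungal pure-culture rows.")
  }
  bact_mean <- colMeans(as.matrix(bact))
  strain_means <- fung %>%
    tidyr::pivot_longer(all_of(peaks), names_to = "peak", values_to = "conc") %>%
    group_by(.data$strain, .data$peak) %>%
    summarise(conc = mean(.data$conc), .groups = "drop") %>%
    group_by(.data$peak) %>%
    summarise(fungal_mean = mean(.data$conc), .groups = "drop")
  fung_mean <- setNames(strain_means$fungal_mean, strain_means$peak)[peaks]
  if (length(peaks) < 2) abort("Need at least two shared peaks.")
  diffs <- bact_mean - fung_mean
  if (sd(diffs) == 0) {
    return(tibble(mean_difference = mean(diffs), statistic = NA_real_,
                  df = length(diffs) - 1,
                  p_value = as.numeric(mean(diffs) == 0), n_peaks = length(peaks)))
  }
  tt <- t.test(bact_mean, fung_mean, paired = TRUE)
  tibble(mean_difference = unname(tt$estimate), statistic = unname(tt$statistic),
         df = unname(tt$parameter), p_value = tt$p.value,
         n_peaks = length(peaks))
}
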