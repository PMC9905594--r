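# Source apportionment of co-culture volatilomes.
#
# Three per-strain linear models decompose the co-culture concentration
# C (per-peak mean corrected concentration) into scaled pure-culture
# contributions, B bacterial and F fungal:
#   model 1:  C = a*B + b*F          over all retained peaks
#   model 2:  C = a*B                over peaks the fungus never touches
#                                    (F = 0, B > 0)
#   model 3:  C - a2*B = b*F         over peaks the fungus produces or
#                                    consumes (F != 0), a2 from model 2
# Coefficients a and b proxy the bacterial and fungal contribution (hence
# growth) in co-culture.  Peaks recurrently misfit across strains are
# candidate interaction-regulated volatiles.

#' Per-strain pure- and co-culture mean volatilomes
#'
#' Computes per-peak means over replicates and time points for the fungal
#' pure culture of `strain` (F), the bacterial pure culture (B), and the
#' strain's co-culture (C), plus the peak subsets used by the three models:
#' `s_bact_only` (B > 0 and F = 0) and `s_fungal` (F != 0).
#'
#' @param corrected A corrected volatilome tibble containing fungal pure,
#'   bacterial pure, and co-culture rows for `strain`.
#' @param strain Strain identifier.
#' @return A list of class `strain_volatilome`: `strain`, `data` (tibble
#'   with columns peak, F, B, C), `s_bact_only`, `s_fungal`.
#' @export
build_strain_set <- function(corrected, strain) {
  validate_volatilome(corrected)
  if (!is_corrected(corrected)) {
    abort("build_strain_set() needs a background-corrected matrix.")
  }
  peaks <- peak_labels(corrected)
  rows_f <- corrected$role == "fungal_pure" & corrected$strain %in% strain
  rows_b <- corrected$role == "bacterial_pure"
  rows_c <- corrected$role == "co_culture" & corrected$strain %in% strain
  for (what in list(c("fungal pure", sum(rows_f)),
                    c("bacterial pure", sum(rows_b)),
                    c("co-culture", sum(rows_c)))) {
    if (as.integer(what[2]) == 0) {
      abort(paste0("No ", what[1], " rows for strain ", strain, "."))
    }
  }
  m <- function(rows) colMeans(as.matrix(corrected[rows, peaks, drop = FALSE]))
  dat <- tibble(peak = peaks, F = unname(m(rows_f)), B = unname(m(rows_b)),
                C = unname(m(rows_c)))
  structure(list(strain = strain, data = dat,
                 s_bact_only = dat$peak[dat$B > 0 & dat$F == 0],
                 s_fungal = dat$peak[dat$F != 0]),
            class = "strain_volatilome")
}

new_decomposition_fit <- function(strain, model, fit, dat, n_vocs,
                                  status = "ok", forced_from = NULL) {
  if (is.null(fit)) {
    return(structure(list(strain = strain, model = model, status = status,
                          coefficients = tibble(), adj_r2 = NA_real_,
                          n_vocs = n_vocs, residuals = tibble()),
                     class = "decomposition_fit"))
  }
  sm <- suppressWarnings(summary(fit))
  cf <- sm$coefficients
  coefs <- tibble(term = rownames(cf), estimate = cf[, "Estimate"],
                  std_error = cf[, "Std. Error"],
                  p_value = cf[, "Pr(>|t|)"])
  # a numerically perfect fit has no residual scale to studentize against
  obs_scale <- mean(abs(stats::fitted(fit))) + mean(abs(stats::residuals(fit)))
  degenerate <- sm$sigma <= 1e-10 * max(obs_scale, .Machine$double.xmin)
  std_res <- if (degenerate) rep(0, length(stats::residuals(fit))) else {
    z <- suppressWarnings(rstudent(fit))
    ifelse(is.finite(z), z, 0)
  }
  structure(list(strain = strain, model = model, status = status,
                 coefficients = coefs,
                 adj_r2 = sm$adj.r.squared,
                 n_vocs = n_vocs,
                 residuals = tibble(peak = dat$peak,
                                    observed = stats::model.frame(fit)[[1]],
                                    fitted = unname(stats::fitted(fit)),
                                    residual = unname(stats::residuals(fit)),
                                    std_residual = unname(std_res)),
                 lm = fit, forced_from = forced_from),
            class = "decomposition_fit")
}

#' @export
print.decomposition_fit <- function(x, ...) {
  cat("Decomposition model", x$model, "for strain", x$strain,
      paste0("(", x$status, ")"), "\n")
  if (x$status == "ok") {
    print(x$coefficients)
    cat("adjusted R^2 =", signif(x$adj_r2, 3), "over", x$n_vocs, "VOCs\n")
  }
  invisible(x)
}

coef_value <- function(fit, term) {
  i <- match(term, fit$coefficients$term)
  if (is.na(i)) NA_real_ else fit$coefficients$estimate[i]
}

check_collinearity <- function(X) {
  k <- kappa(X, exact = TRUE)
  if (!is.finite(k) || k > 1e10) {
    abort(paste0("Predictors are collinear beyond tolerance ",
                 "(condition number ", format(k, digits = 3), ")."))
  }
}

#' Fit the two-source decomposition (model 1)
#'
#' Least squares of the co-culture means C on the bacterial (B) and fungal
#' (F) pure-culture means over all retained peaks, intercept included (it is
#' reported and expected to be indistinguishable from zero when the additive
#' assumption holds).
#'
#' @param set A `strain_volatilome` from [build_strain_set()].
#' @param through_origin Suppress the intercept.
#' @return A `decomposition_fit`; see [tidy.decomposition_fit()].
#' @export
fit_model1 <- function(set, through_origin = FALSE) {
  stopifnot(inherits(set, "strain_volatilome"))
  dat <- set$data
  if (nrow(dat) <= 3) abort("Model 1 needs more than 3 peaks.")
  check_collinearity(cbind(dat$B, dat$F))
  fml <- if (through_origin) C ~ B + F - 1 else C ~ B + F
  fit <- lm(fml, data = dat)
  new_decomposition_fit(set$strain, 1L, fit, dat, nrow(dat))
}

#' Fit the bacterial-only decomposition (model 2)
#'
#' Least squares of C on B restricted to peaks produced by the bacterium and
#' never produced or consumed by the fungal strain (corrected fungal mean
#' exactly zero).  When the subset has fewer than 3 peaks the fit is skipped
#' with an explicit status rather than an error.
#'
#' @inheritParams fit_model1
#' @export
fit_model2 <- function(set, through_origin = FALSE) {
  stopifnot(inherits(set, "strain_volatilome"))
  dat <- set$data[set$data$peak %in% set$s_bact_only, , drop = FALSE]
  if (nrow(dat) < 3) {
    return(new_decomposition_fit(set$strain, 2L, NULL, NULL, nrow(dat),
                                 status = "skipped_small_subset"))
  }
  fml <- if (through_origin) C ~ B - 1 else C ~ B
  fit <- lm(fml, data = dat)
  new_decomposition_fit(set$strain, 2L, fit, dat, nrow(dat))
}

#' Fit the fungal-only decomposition (model 3)
#'
#' Uses the model-2 bacterial coefficient to predict the bacterial share of
#' each co-culture concentration, subtracts it, and regresses the remainder
#' `R = C - a2*B` on the fungal pure-culture means F over the peaks the
#' fungus produces or consumes.  Model 3 is fitted regardless of the
#' significance of the model-2 coefficient; the upstream status is carried
#' in the result.
#'
#' @inheritParams fit_model1
#' @param model2 The strain's model-2 `decomposition_fit`.
#' @export
fit_model3 <- function(set, model2, through_origin = FALSE) {
  stopifnot(inherits(set, "strain_volatilome"))
  if (missing(model2) || !inherits(model2, "decomposition_fit") ||
      model2$model != 2L || model2$status != "ok") {
    abort("Fit model 2 first; model 3 needs its bacterial coefficient.")
  }
  a2 <- coef_value(model2, "B")
  dat <- set$data[set$data$peak %in% set$s_fungal, , drop = FALSE]
  if (nrow(dat) <= 2) abort("Model 3 needs more than 2 fungal peaks.")
  dat$R <- dat$C - a2 * dat$B
  fml <- if (through_origin) R ~ F - 1 else R ~ F
  fit <- lm(fml, data = dat)
  m2_sig <- model2$coefficients$p_value[match("B", model2$coefficients$term)]
  new_decomposition_fit(set$strain, 3L, fit, dat, nrow(dat),
                        forced_from = m2_sig)
}

#' Fit all three decomposition models for every strain
#'
#' @param corrected A corrected volatilome tibble.
#' @param strains Strains to fit; defaults to all strains with co-culture
#'   rows.
#' @param through_origin Suppress intercepts in all models.
#' @return A list of `decomposition_fit` objects (up to 3 per strain).
#' @export
fit_decomposition <- function(corrected, strains = NULL,
                              through_origin = FALSE) {
  if (is.null(strains)) {
    strains <- sort(unique(corrected$strain[corrected$role == "co_culture"]))
  }
  fits <- list()
  for (s in strains) {
    set <- build_strain_set(corrected, s)
    m1 <- fit_model1(set, through_origin)
    m2 <- fit_model2(set, through_origin)
    fits <- c(fits, list(m1, m2))
    if (m2$status == "ok" && length(set$s_fungal) > 2) {
      fits <- c(fits, list(fit_model3(set, m2, through_origin)))
    }
  }
  fits
}

#' @describeIn fit_decomposition Wide per-strain coefficient table in the
#'   layout of a published coefficient table: coefficient, SE, significance
#'   stars (* p < 0.05, ** p < 0.001), adjusted R-squared and #VOCs per
#'   model.
#' @param fits A list of `decomposition_fit` objects.
#' @export
decomposition_table <- function(fits) {
  rows <- lapply(fits, function(f) {
    if (f$status != "ok") {
      return(tibble(strain = f$strain, model = f$model, term = NA_character_,
                    estimate = NA_real_, std_error = NA_real_,
                    p_value = NA_real_, stars = "",
                    adj_r2 = NA_real_, n_vocs = f$n_vocs))
    }
    cf <- f$coefficients[f$coefficients$term != "(Intercept)", , drop = FALSE]
    tibble(strain = f$strain, model = f$model, term = cf$term,
           estimate = cf$estimate, std_error = cf$std_error,
           p_value = cf$p_value,
           stars = ifelse(cf$p_value < 0.001, "**",
                          ifelse(cf$p_value < 0.05, "*", "ns")),
           adj_r2 = f$adj_r2, n_vocs = f$n_vocs)
  })
  bind_rows(rows)
}

#' Detect potentially regulated volatiles from recurrent residual outliers
#'
#' Counts, per peak, the strain-models in which the magnitude of the
#' (externally studentized) standardized residual exceeds `outlier_z`.
#' Peaks flagged in at least `min_frequency` strain-models are reported with
#' their per-strain deviation signs (measured above or below the additive
#' prediction) and a per-species direction summary.
#'
#' @param fits A list of `decomposition_fit` objects with residuals
#'   (typically the model-1 fits of all strains).
#' @param outlier_z Standardized-residual cutoff.
#' @param min_frequency Minimum number of flagging strain-models; defaults
#'   to `ceiling(0.25 * number of fits)`.
#' @param species Optional named vector mapping strain to species for the
#'   direction summary.
#' @return A tibble: `peak`, `frequency`, `n_models`, `direction`
#'   (`"above"`/`"below"`/`"mixed"` prediction), with per-strain signs in
#'   the `detail` attribute.
#' @export
detect_regulated_vocs <- function(fits, outlier_z = 2, min_frequency = NULL,
                                  species = NULL) {
  fits <- Filter(function(f) f$status == "ok" && nrow(f$residuals) > 0, fits)
  if (!length(fits)) abort("Need at least one fit with residuals.")
  if (is.null(min_frequency)) min_frequency <- ceiling(0.25 * length(fits))
  flags <- bind_rows(lapply(fits, function(f) {
    r <- f$residuals
    tibble(strain = f$strain, model = f$model, peak = r$peak,
           std_residual = r$std_residual,
           flagged = abs(r$std_residual) > outlier_z,
           sign = sign(r$residual))
  }))
  counts <- flags %>%
    group_by(.data$peak) %>%
    summarise(frequency = sum(.data$flagged),
              n_models = n(),
              direction = {
        s <- .data$sign[.data$flagged]
        if (!length(s)) NA_character_
        else if (all(s > 0)) "above"
        else if (all(s < 0)) "below"
        else "mixed"
      }, .groups = "drop") %>%
    filter(.data$frequency >= min_frequency) %>%
    arrange(dplyr::desc(.data$frequency))
  detail <- flags[flags$flagged & flags$peak %in% counts$peak, ]
  if (!is.null(species)) detail$species <- unname(species[detail$strain])
  attr(counts, "detail") <- detail
  attr(counts, "min_frequency") <- min_frequency
  counts
}

#' Cross-model coefficient correlations
#'
#' Pearson and Spearman correlations between the model-1 and model-2
#' bacterial coefficients and between the model-1 and model-3 fungal
#' coefficients across strains.  Accepts either a list of
#' `decomposition_fit`s or a tibble with columns `bacterial_m1`,
#' `bacterial_m2`, `fungal_m1`, `fungal_m3` (e.g. a published coefficient
#' table).
#'
#' @param fits List of fits or a coefficient tibble as above.
#' @return A tibble: `pair`, `method`, `r`, `p_value`, `n`.
#' @export
coefficient_correlations <- function(fits) {
  if (is.data.frame(fits)) {
    wide <- fits
  } else {
    tab <- decomposition_table(fits)
    pick <- function(model, term) {
      x <- tab[tab$model == model & tab$term == term, c("strain", "estimate")]
      setNames(x$estimate, x$strain)
    }
    a1 <- pick(1, "B"); b1 <- pick(1, "F")
    a2 <- pick(2, "B"); b3 <- pick(3, "F")
    strains <- Reduce(intersect, list(names(a1), names(a2), names(b1)))
    wide <- tibble(strain = strains,
                   bacterial_m1 = unname(a1[strains]),
                   bacterial_m2 = unname(a2[strains]),
                   fungal_m1 = unname(b1[strains]),
                   fungal_m3 = unname(b3[strains]))
  }
  pairs <- list(
    bacterial_m1_vs_m2 = c("bacterial_m1", "bacterial_m2"),
    fungal_m1_vs_m3 = c("fungal_m1", "fungal_m3"))
  out <- list()
  for (nm in names(pairs)) {
    x <- wide[[pairs[[nm]][1]]]; y <- wide[[pairs[[nm]][2]]]
    ok <- stats::complete.cases(x, y)
    if (sum(ok) < 4) abort(paste0("Fewer than 4 strains with both ",
                                  "coefficients for ", nm, "."))
    for (m in c("pearson", "spearman")) {
      ct <- suppressWarnings(cor.test(x[ok], y[ok], method = m))
      out[[length(out) + 1]] <- tibble(pair = nm, method = m,
                                       r = unname(ct$estimate),
                                       p_value = ct$p.value, n = sum(ok))
    }
  }
  bind_rows(out)
}

#' @rdname tidiers
#' @export
tidy.decomposition_fit <- function(x, ...) {
  if (x$status != "ok") return(tibble())
  mutate(x$coefficients, strain = x$strain, model = x$model,
         .before = 1)
}

#' @rdname tidiers
#' @export
glance.decomposition_fit <- function(x, ...) {
  tibble(strain = x$strain, model = x$model, status = x$status,
         adj_r2 = x$adj_r2, n_vocs = x$n_vocs)
}

#' Broom-style accessors for fitted objects
#'
#' `tidy()` returns coefficient-level summaries, `glance()` one-row model
#' summaries, `augment()` per-peak residual diagnostics.
#'
#' @param x A fitted object from this package.
#' @param ... Unused.
#' @name tidiers
#' @rdname tidiers
#' @export
augment.decomposition_fit <- function(x, ...) {
  if (x$status != "ok") return(tibble())
  mutate(x$residuals, strain = x$strain, model = x$model, .before = 1)
}
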