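# Linear discriminant analysis of volatilomes: prediction of taxonomy and
# cultivation mode, variable-association scores on the retained linear
# discriminants, and centroid distances between pure and co-cultures.

lda_labels <- function(data, factor) {
  mode <- case_when(data$role %in% c("fungal_pure", "bacterial_pure") ~ "pure",
                    data$role == "co_culture" ~ "co",
                    TRUE ~ NA_character_)
  switch(factor,
         species = ifelse(data$role == "bacterial_pure", "bacterium",
                          data$species),
         strain = ifelse(data$role == "bacterial_pure", "bacterium",
                         data$strain),
         mode = mode,
         species_mode = paste(ifelse(data$role == "bacterial_pure",
                                     "bacterium", data$species), mode,
                              sep = ":"),
         strain_mode = paste(ifelse(data$role == "bacterial_pure",
                                    "bacterium", data$strain), mode,
                             sep = ":"))
}

#' Train a linear discriminant model on volatilomes
#'
#' Each measurement row (sample x time point) of the culture rows is one
#' observation; the class is the chosen experimental factor (species,
#' strain, cultivation mode, or a factor x mode combination).  Rows are
#' split into a stratified seeded training fraction and a held-out test set
#' so both represent all sample groups; peaks are centred and scaled to unit
#' variance using training statistics only (near-constant training peaks are
#' dropped); the discriminant model is fitted on the training rows and its
#' accuracy measured on the held-out rows.  Only discriminants carrying at
#' least `min_ld_variance` of the between-class variance are retained for
#' interpretation.
#'
#' @param corrected A corrected volatilome tibble.
#' @param factor One of `"species"`, `"strain"`, `"mode"`,
#'   `"species_mode"`, `"strain_mode"`.
#' @param train_fraction Training proportion in (0, 1).
#' @param seed Integer seed for the split.
#' @param min_ld_variance Minimum variance share of a retained LD.
#' @return A list with `model` (class `vol_lda`) and `assessment` (tibble:
#'   factor, n_correct, n_test, accuracy).
#' @export
train_lda <- function(corrected, factor = c("species", "strain", "mode",
                                            "species_mode", "strain_mode"),
                      train_fraction = 0.7, seed = 1L,
                      min_ld_variance = 0.1) {
  validate_volatilome(corrected)
  factor <- arg_match(factor)
  stopifnot(train_fraction > 0, train_fraction < 1)
  keep_roles <- if (factor == "species") {
    c("fungal_pure", "co_culture", "bacterial_pure")
  } else c("fungal_pure", "co_culture")
  data <- corrected[corrected$role %in% keep_roles, , drop = FALSE]
  data$.class <- lda_labels(data, factor)
  data <- data[!is.na(data$.class), , drop = FALSE]
  classes <- unique(data$.class)
  if (length(classes) < 2) abort("Need at least two classes.")

  peaks <- peak_labels(data)
  x <- as.matrix(data[peaks])
  set.seed(as.integer(seed))
  for (attempt in seq_len(10)) {
    train_idx <- unlist(lapply(classes, function(cl) {
      rows <- which(data$.class == cl)
      n_tr <- max(2, round(train_fraction * length(rows)))
      if (n_tr >= length(rows)) n_tr <- length(rows) - 1
      sample(rows, n_tr)
    }))
    tab <- table(data$.class[train_idx])
    if (all(classes %in% names(tab)) && all(tab >= 2)) break
    warn("Redrawing training split: a class was underrepresented.")
    if (attempt == 10) abort("Could not build a stratified training split.")
  }
  test_idx <- setdiff(seq_len(nrow(data)), train_idx)
  if (!length(test_idx)) abort("Held-out test set is empty.")

  centers <- colMeans(x[train_idx, , drop = FALSE])
  sds <- apply(x[train_idx, , drop = FALSE], 2, sd)
  kept <- sds > 1e-6
  if (!all(kept)) {
    inform(paste0("Dropping ", sum(!kept),
                  " near-constant peak(s) before scaling."))
  }
  scale_rows <- function(idx) {
    sweep(sweep(x[idx, kept, drop = FALSE], 2, centers[kept]), 2, sds[kept],
          "/")
  }
  fit <- MASS::lda(scale_rows(train_idx),
                   grouping = factor(data$.class[train_idx]))
  var_share <- fit$svd^2 / sum(fit$svd^2)
  pred <- predict(fit, scale_rows(test_idx))$class
  n_correct <- sum(as.character(pred) == data$.class[test_idx])
  assessment <- tibble(factor = factor, n_correct = n_correct,
                       n_test = length(test_idx),
                       accuracy = n_correct / length(test_idx))
  model <- structure(list(
    lda = fit, factor = factor, classes = sort(classes),
    peaks = peaks[kept], centers = centers[kept], sds = sds[kept],
    var_share = var_share,
    retained_lds = which(var_share >= min_ld_variance),
    min_ld_variance = min_ld_variance,
    train_keys = paste(data$sample_id[train_idx], data$time_point[train_idx]),
    assessment = assessment, seed = as.integer(seed)),
    class = "vol_lda")
  list(model = model, assessment = assessment)
}

#' @export
print.vol_lda <- function(x, ...) {
  cat("Volatilome LDA of", x$factor, "with", length(x$classes), "classes;",
      length(x$retained_lds), "LD(s) at >=",
      100 * x$min_ld_variance, "% variance\n")
  print(x$assessment)
  invisible(x)
}

#' Project volatilome rows into a model's discriminant space
#' @keywords internal
lda_scores <- function(model, data) {
  x <- as.matrix(data[model$peaks])
  scaled <- sweep(sweep(x, 2, model$centers), 2, model$sds, "/")
  scaled %*% model$lda$scaling
}

#' Peaks most associated with each retained discriminant
#'
#' The association score of a peak with an LD is its coefficient in the
#' (standardized) discriminant scaling.  Per retained LD, peaks whose score
#' lies strictly beyond the lower or upper `tail` quantile of the score
#' distribution are reported with the sign of their association.
#'
#' @param model A `vol_lda` model.
#' @param tail Proportion of each end of the score distribution, in
#'   (0, 0.5).
#' @return A tibble: `ld`, `peak`, `score`, `sign`.
#' @export
variable_associations <- function(model, tail = 0.05) {
  stopifnot(inherits(model, "vol_lda"), tail > 0, tail < 0.5)
  if (!length(model$retained_lds)) {
    warn("No discriminant reaches the minimum variance share.")
    return(tibble(ld = integer(0), peak = character(0),
                  score = numeric(0), sign = numeric(0)))
  }
  out <- lapply(model$retained_lds, function(ld) {
    sc <- model$lda$scaling[, ld]
    lo <- quantile(sc, tail); hi <- quantile(sc, 1 - tail)
    ext <- sc < lo | sc > hi
    tibble(ld = ld, peak = names(sc)[ext], score = unname(sc[ext]),
           sign = sign(unname(sc[ext])))
  })
  arrange(bind_rows(out), .data$ld, dplyr::desc(abs(.data$score)))
}

#' Centroid distances between pure and co-cultures in discriminant space
#'
#' Projects all fungal culture rows onto the model's discriminants and
#' computes, per strain, the Euclidean distance (across all model LDs)
#' between the centroid of its pure-culture rows and the centroid of its
#' co-culture rows.
#'
#' @param model A `vol_lda` model.
#' @param corrected The corrected volatilome tibble to project.
#' @return A tibble: `strain`, `distance`, `n_pure`, `n_co`.
#' @export
centroid_distances <- function(model, corrected) {
  stopifnot(inherits(model, "vol_lda"))
  validate_volatilome(corrected)
  data <- corrected[corrected$role %in% c("fungal_pure", "co_culture"), ,
                    drop = FALSE]
  scores <- lda_scores(model, data)
  out <- list()
  for (s in sort(unique(data$strain))) {
    pure <- data$strain == s & data$role == "fungal_pure"
    co <- data$strain == s & data$role == "co_culture"
    if (!any(pure) || !any(co)) {
      warn(paste0("Strain ", s, " lacks a cultivation mode; skipped."))
      next
    }
    d <- sqrt(sum((colMeans(scores[pure, , drop = FALSE]) -
                     colMeans(scores[co, , drop = FALSE]))^2))
    out[[length(out) + 1]] <- tibble(strain = s, distance = d,
                                     n_pure = sum(pure), n_co = sum(co))
  }
  bind_rows(out)
}

#' @rdname tidiers
#' @export
glance.vol_lda <- function(x, ...) {
  mutate(x$assessment, n_classes = length(x$classes),
         n_retained_lds = length(x$retained_lds))
}
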