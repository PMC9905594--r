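# Raw peak-table filtering: blank screen, autocorrelation screen, detection
# thresholds, and the time-stability screen.

welch_p <- function(x, y) {
  # Welch two-sample p-value with guards for zero-variance groups
  nx <- length(x); ny <- length(y)
  if (nx < 2 || ny < 2) return(NA_real_)
  vx <- var(x); vy <- var(y)
  if (vx == 0 && vy == 0) return(if (mean(x) == mean(y)) 1 else 0)
  se2 <- vx / nx + vy / ny
  t_stat <- (mean(x) - mean(y)) / sqrt(se2)
  df <- se2^2 / ((vx / nx)^2 / (nx - 1) + (vy / ny)^2 / (ny - 1))
  2 * pt(-abs(t_stat), df)
}

new_filter_report <- function(n_input, removed_blank = character(0),
                              removed_autocorrelated = tibble(
                                kept = character(0), removed = character(0),
                                r = numeric(0))) {
  n_removed <- length(removed_blank) + nrow(removed_autocorrelated)
  structure(list(n_input = n_input,
                 removed_blank = removed_blank,
                 removed_autocorrelated = removed_autocorrelated,
                 n_retained = n_input - n_removed),
            class = "filter_report")
}

#' @export
print.filter_report <- function(x, ...) {
  cat("Peak filter report:", x$n_input, "peaks in,", x$n_retained, "retained\n")
  cat("  removed as blank-indistinguishable:", length(x$removed_blank), "\n")
  cat("  removed as autocorrelated:", nrow(x$removed_autocorrelated), "\n")
  invisible(x)
}

#' Remove peaks indistinguishable from empty-vial blanks
#'
#' Per peak, a Welch two-sample test compares all non-blank measurements
#' against the empty-blank measurements (pooled across groups); peaks whose
#' p-value is at or above `alpha` are removed.
#'
#' @param data An uncorrected volatilome tibble containing `empty_blank`
#'   rows and at least one non-blank row.
#' @param alpha Significance level.
#' @return A list with `data` (filtered volatilome) and `report`
#'   (a `filter_report`).
#' @export
filter_blank_peaks <- function(data, alpha = 0.05) {
  validate_volatilome(data)
  blanks <- data$role == "empty_blank"
  if (!any(blanks)) {
    abort(paste0("No empty_blank rows present; skip the blank screen ",
                 "explicitly if your data carry no empty-vial blanks."))
  }
  if (all(blanks)) abort("No non-blank rows present.")
  peaks <- peak_labels(data)
  p <- vapply(peaks, function(pk) {
    welch_p(data[[pk]][!blanks], data[[pk]][blanks])
  }, numeric(1))
  keep <- !is.na(p) & p < alpha
  removed <- peaks[!keep]
  out <- data[, setdiff(names(data), removed)]
  out <- mark_corrected(out, is_corrected(data))
  list(data = out,
       report = new_filter_report(length(peaks), removed_blank = removed))
}

#' Remove highly autocorrelated peaks
#'
#' Computes pairwise Pearson correlations across all measurement rows;
#' within each connected group of peak pairs with `|r| > r_cut` exactly one
#' peak is kept -- the one with the lowest m/z, since the removed members of
#' such groups are typically isotopologues of a lighter monoisotopic peak.
#' Constant columns have undefined correlations and are treated as
#' uncorrelated (with a warning).
#'
#' @param data A volatilome tibble with at least two peaks.
#' @param r_cut Absolute correlation bound in (0, 1].
#' @return A list with `data` and `report` as in [filter_blank_peaks()].
#' @export
filter_autocorrelated_peaks <- function(data, r_cut = 0.99) {
  validate_volatilome(data)
  stopifnot(r_cut > 0, r_cut <= 1)
  peaks <- peak_labels(data)
  if (length(peaks) < 2) abort("Need at least two peaks.")
  vals <- as.matrix(data[peaks])
  const <- apply(vals, 2, function(v) var(v) == 0)
  if (any(const)) {
    warn(paste0("Constant peak column(s) treated as uncorrelated: ",
                paste(peaks[const], collapse = ", ")))
  }
  cm <- suppressWarnings(cor(vals))
  cm[is.na(cm)] <- 0
  diag(cm) <- 0
  hits <- which(abs(cm) > r_cut & upper.tri(cm), arr.ind = TRUE)

  # union-find over peaks so chains A~B~C collapse to one component
  parent <- seq_along(peaks)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (k in seq_len(nrow(hits))) {
    ri <- find(hits[k, 1]); rj <- find(hits[k, 2])
    if (ri != rj) parent[max(ri, rj)] <- min(ri, rj)
  }
  comp <- vapply(seq_along(peaks), find, integer(1))
  mzs <- peak_mz(peaks)
  removed <- character(0)
  detail <- list()
  for (cid in unique(comp[duplicated(comp) | duplicated(comp, fromLast = TRUE)])) {
    members <- which(comp == cid)
    keep <- members[which.min(mzs[members])]
    drop <- setdiff(members, keep)
    removed <- c(removed, peaks[drop])
    detail[[length(detail) + 1]] <- tibble(
      kept = peaks[keep], removed = peaks[drop],
      r = cm[cbind(rep(keep, length(drop)), drop)])
  }
  detail <- if (length(detail)) bind_rows(detail) else
    tibble(kept = character(0), removed = character(0), r = numeric(0))
  out <- data[, setdiff(names(data), removed)]
  out <- mark_corrected(out, is_corrected(data))
  list(data = out,
       report = new_filter_report(length(peaks),
                                  removed_autocorrelated = detail))
}

#' Apply a detection threshold
#'
#' Sets concentrations whose magnitude is below `threshold` to zero; for
#' corrected tables the rule applies to the absolute value, so small
#' consumption values are zeroed symmetrically with small production values.
#' Idempotent, and monotone in the threshold.
#'
#' @param data A volatilome tibble.
#' @param threshold Detection limit (ppbV), non-negative.
#' @return The thresholded volatilome tibble.
#' @export
apply_threshold <- function(data, threshold) {
  validate_volatilome(data)
  if (!is.numeric(threshold) || length(threshold) != 1 || threshold < 0) {
    abort("Threshold must be a single non-negative number (ppbV).")
  }
  peaks <- peak_labels(data)
  corrected <- is_corrected(data)
  for (pk in peaks) {
    v <- data[[pk]]
    v[abs(v) < threshold] <- 0
    data[[pk]] <- v
  }
  mark_corrected(data, corrected)
}

#' Screen peaks for concentration trends over time
#'
#' Fits, per peak, a straight line of concentration on the integer
#' time-point index over all non-empty-blank rows and reports the slope,
#' its p-value, and the share of variance attributable to time
#' (the regression R-squared, in percent).
#'
#' @param data A volatilome tibble measured at two or more time points.
#' @return A tibble with columns `peak`, `slope`, `p_value`,
#'   `pct_variance`.
#' @export
analyze_time_stability <- function(data) {
  validate_volatilome(data)
  rows <- data$role != "empty_blank"
  tp <- data$time_point[rows]
  if (length(unique(tp)) < 2) abort("Need at least two time points.")
  peaks <- peak_labels(data)
  n <- length(tp)
  tc <- tp - mean(tp)
  sxx <- sum(tc^2)
  res <- lapply(peaks, function(pk) {
    y <- data[[pk]][rows]
    slope <- sum(tc * (y - mean(y))) / sxx
    fitted <- mean(y) + slope * tc
    sse <- sum((y - fitted)^2)
    sst <- sum((y - mean(y))^2)
    if (sst == 0) {
      return(tibble(peak = pk, slope = 0, p_value = 1, pct_variance = 0))
    }
    se <- sqrt(sse / (n - 2) / sxx)
    p <- if (se == 0) 0 else 2 * pt(-abs(slope / se), n - 2)
    tibble(peak = pk, slope = slope, p_value = p,
           pct_variance = 100 * (1 - sse / sst))
  })
  bind_rows(res)
}
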