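# Growth-medium (PDA) null-distribution background correction.
#
# The 3 medium-blank vials x 4 time points give 12 null measurements per
# peak.  Peaks whose blank concentration trends with time get a model-drawn
# null instead: 12 seeded draws from Normal(predicted concentration at the
# sample's own time point, residual sd).  Each individual sample measurement
# is then tested against its peak's null; significant measurements become
# signed differences from the null mean (production positive, consumption
# negative), insignificant ones become zero.

#' Build the medium-blank null distribution per peak
#'
#' Fits, per peak, a straight line of blank concentration on time point.
#' If the slope is insignificant at `alpha`, the null is the observed blank
#' values themselves (`source = "observed"`, one pool for all time points).
#' If significant, the null is drawn from a normal with the model-predicted
#' mean at each time point and the residual standard deviation
#' (`source = "model_drawn"`, one pool per time point, seeded).
#'
#' @param data An uncorrected volatilome tibble with medium-blank rows
#'   (at least 12 blank measurements, e.g. 3 vials x 4 time points).
#' @param alpha Significance level for the time-trend test.
#' @param seed Integer seed for the model-drawn pools.
#' @return A list of class `pda_null` with `summary` (tibble: peak, source,
#'   mean, sd, slope, slope_p) and `values` (tibble: peak, time_point
#'   -- `NA` for observed pools -- and 12 `value`s per pool).
#' @export
build_pda_null <- function(data, alpha = 0.05, seed = 1L) {
  validate_volatilome(data)
  if (is_corrected(data)) abort("Nulls must be built from uncorrected data.")
  blanks <- data[data$role == "medium_blank", , drop = FALSE]
  if (nrow(blanks) < 12) {
    abort(paste0("Need at least 12 medium-blank measurements (have ",
                 nrow(blanks), ")."))
  }
  peaks <- peak_labels(data)
  tps <- sort(unique(data$time_point))
  set.seed(as.integer(seed))
  n_null <- nrow(blanks)
  summaries <- vector("list", length(peaks))
  values <- vector("list", length(peaks))
  for (i in seq_along(peaks)) {
    pk <- peaks[i]
    y <- blanks[[pk]]
    t <- blanks$time_point
    fit <- lm(y ~ t)
    sm <- suppressWarnings(summary(fit))  # synthetic blanks can fit exactly
    cf <- sm$coefficients
    slope <- cf["t", "Estimate"]
    slope_p <- if (nrow(cf) > 1) cf["t", "Pr(>|t|)"] else 1
    if (is.na(slope_p)) slope_p <- 1
    if (slope_p < alpha) {
      sigma <- sm$sigma
      vals <- bind_rows(lapply(tps, function(tt) {
        mu <- unname(coef(fit)[1] + coef(fit)[2] * tt)
        tibble(peak = pk, time_point = tt,
               value = rnorm(n_null, mu, sigma))
      }))
      src <- "model_drawn"
    } else {
      vals <- tibble(peak = pk, time_point = NA_integer_, value = y)
      src <- "observed"
    }
    summaries[[i]] <- tibble(peak = pk, source = src,
                             mean = mean(y), sd = sd(y),
                             slope = slope, slope_p = slope_p)
    values[[i]] <- vals
  }
  structure(list(summary = bind_rows(summaries), values = bind_rows(values)),
            class = "pda_null")
}

#' Mean medium-blank concentration per peak
#'
#' @param nulls A `pda_null` object.
#' @return Named numeric vector of per-peak null means.
#' @export
pda_means <- function(nulls) {
  stopifnot(inherits(nulls, "pda_null"))
  setNames(nulls$summary$mean, nulls$summary$peak)
}

#' Correct a concentration table against the medium null
#'
#' Tests every individual measurement against its peak's 12-point null and
#' replaces it by the signed difference from the null mean when significant
#' (positive = production above the medium, negative = consumption), by zero
#' otherwise.  The default test asks whether the measurement is a plausible
#' single draw from the null distribution (prediction-interval form,
#' `t = (x - mean) / (sd * sqrt(1 + 1/n))`, df `n - 1`), which holds the
#' false-nonzero rate at `alpha`; `method = "mean"` instead compares the
#' measurement to the null mean with standard error `sd/sqrt(n)` (far more
#' liberal).  No detection threshold is applied here -- thresholds belong
#' downstream.
#'
#' @param data An uncorrected volatilome tibble covering the same peaks as
#'   `nulls`.
#' @param nulls A `pda_null` from [build_pda_null()].
#' @param alpha Significance level.
#' @param method `"prediction"` (default) or `"mean"`; see Details.
#' @param two_sided Two-sided test (default) or one-sided.
#' @return The corrected volatilome tibble (`corrected` flag set; negative
#'   values encode consumption).
#' @export
correct_matrix <- function(data, nulls, alpha = 0.05,
                           method = c("prediction", "mean"),
                           two_sided = TRUE) {
  validate_volatilome(data)
  method <- arg_match(method)
  if (is_corrected(data)) {
    abort("Matrix is already corrected; re-correction is not meaningful.")
  }
  stopifnot(inherits(nulls, "pda_null"))
  peaks <- peak_labels(data)
  missing <- setdiff(peaks, nulls$summary$peak)
  if (length(missing)) {
    abort(paste0("Nulls missing for peak(s): ",
                 paste(head(missing, 3), collapse = ", ")))
  }
  zero_sd_hits <- 0L
  for (pk in peaks) {
    pool <- nulls$values[nulls$values$peak == pk, , drop = FALSE]
    x <- data[[pk]]
    out <- numeric(length(x))
    by_time <- !all(is.na(pool$time_point))
    for (tt in if (by_time) sort(unique(data$time_point)) else NA) {
      rows <- if (by_time) which(data$time_point == tt) else seq_along(x)
      nv <- if (by_time) pool$value[pool$time_point == tt] else pool$value
      m0 <- mean(nv); s0 <- sd(nv); n0 <- length(nv)
      if (s0 == 0) {
        sig <- x[rows] != m0
        zero_sd_hits <- zero_sd_hits + sum(sig)
      } else {
        se <- if (method == "prediction") s0 * sqrt(1 + 1 / n0) else s0 / sqrt(n0)
        t_stat <- (x[rows] - m0) / se
        p <- pt(-abs(t_stat), n0 - 1) * (if (two_sided) 2 else 1)
        sig <- p < alpha
      }
      out[rows] <- ifelse(sig, x[rows] - m0, 0)
    }
    data[[pk]] <- out
  }
  if (zero_sd_hits > 0) {
    warn(paste0(zero_sd_hits, " measurement(s) declared significant against ",
                "a zero-variance null by convention."))
  }
  mark_corrected(data, TRUE)
}
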