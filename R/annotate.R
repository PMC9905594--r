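# Annotation confirmation: linear retention indices from an n-alkane ladder
# and PTR<->GC-MS cross-correlation of tentatively annotated peaks.

#' Linear retention index by alkane-ladder interpolation
#'
#' Interpolates a retention time linearly between the bracketing n-alkanes:
#' `LRI = 100 * (n + (rt - rt_n) / (rt_(n+1) - rt_n))` where `n` is the
#' carbon number of the alkane eluting at or before `rt`.  Retention times
#' outside the ladder range are an error (no extrapolation).
#'
#' @param rt Numeric vector of retention times (min).
#' @param ladder Tibble or data frame with columns `carbon` and `rt`, both
#'   strictly increasing (e.g. a C7-C30 alkane series).
#' @return Numeric vector of retention indices.
#' @examples
#' ladder <- tibble::tibble(carbon = 9:11, rt = c(10, 12, 15))
#' compute_lri(11, ladder)  # 950
#' @export
compute_lri <- function(rt, ladder) {
  stopifnot(is.data.frame(ladder), all(c("carbon", "rt") %in% names(ladder)))
  ladder <- ladder[order(ladder$carbon), , drop = FALSE]
  if (any(diff(ladder$carbon) <= 0) || any(diff(ladder$rt) <= 0)) {
    abort("Alkane ladder must be strictly increasing in carbon and rt.")
  }
  if (any(rt < min(ladder$rt)) || any(rt > max(ladder$rt))) {
    abort("Retention time outside the alkane ladder; no extrapolation.")
  }
  idx <- findInterval(rt, ladder$rt, rightmost.closed = TRUE)
  n <- ladder$carbon[idx]
  rt_n <- ladder$rt[idx]
  rt_n1 <- ladder$rt[idx + 1]
  span <- ladder$carbon[idx + 1] - n
  100 * (n + span * (rt - rt_n) / (rt_n1 - rt_n))
}

#' Confirm tentative peak annotations against GC-MS quantities
#'
#' Matches mass peaks to GC-MS compounds by identical annotation name
#' (case-insensitive) and correlates, across shared samples, the mean peak
#' concentration with the GC-MS quantity (Pearson and Spearman).  An
#' annotation is `confirmed` when the correlation is significant at
#' `alpha` -- by default when either method is significant; `rule = "both"`
#' requires both.  Insignificant matches stay `tentative`.
#'
#' @param ptr_means Tibble with columns `sample_id`, `annotation`,
#'   `concentration` (mean peak concentration per sample) and optionally
#'   `peak`.
#' @param gc Tibble with columns `sample_id`, `compound`, `quantity`.
#' @param alpha Significance level.
#' @param rule `"either"` (default) or `"both"`.
#' @return A tibble: `annotation`, `peak` (if supplied), `n_samples`,
#'   `pearson_r`, `pearson_p`, `spearman_r`, `spearman_p`, `status`.
#' @export
confirm_annotations <- function(ptr_means, gc, alpha = 0.05,
                                rule = c("either", "both")) {
  rule <- arg_match(rule)
  stopifnot(all(c("sample_id", "annotation", "concentration") %in%
                  names(ptr_means)),
            all(c("sample_id", "compound", "quantity") %in% names(gc)))
  ptr_means$key <- tolower(trimws(ptr_means$annotation))
  gc$key <- tolower(trimws(gc$compound))
  shared <- intersect(unique(ptr_means$key), unique(gc$key))
  shared <- shared[nzchar(shared)]
  if (!length(shared)) {
    warn("No annotation names match any GC-MS compound.")
    return(tibble(annotation = character(0), n_samples = integer(0),
                  pearson_r = numeric(0), pearson_p = numeric(0),
                  spearman_r = numeric(0), spearman_p = numeric(0),
                  status = character(0)))
  }
  out <- lapply(shared, function(k) {
    p <- ptr_means[ptr_means$key == k, , drop = FALSE]
    g <- gc[gc$key == k, , drop = FALSE]
    merged <- dplyr::inner_join(p, g, by = "sample_id",
                                relationship = "many-to-many")
    if (nrow(merged) < 4) {
      abort(paste0("Fewer than 4 shared samples for annotation '",
                   p$annotation[1], "'."))
    }
    pe <- suppressWarnings(cor.test(merged$concentration, merged$quantity,
                                    method = "pearson"))
    sp <- suppressWarnings(cor.test(merged$concentration, merged$quantity,
                                    method = "spearman"))
    sig <- if (rule == "either") pe$p.value < alpha || sp$p.value < alpha
           else pe$p.value < alpha && sp$p.value < alpha
    res <- tibble(annotation = p$annotation[1], n_samples = nrow(merged),
                  pearson_r = unname(pe$estimate), pearson_p = pe$p.value,
                  spearman_r = unname(sp$estimate), spearman_p = sp$p.value,
                  status = if (isTRUE(sig)) "confirmed" else "tentative")
    if ("peak" %in% names(p)) res <- mutate(res, peak = p$peak[1], .after = 1)
    res
  })
  bind_rows(out)
}
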