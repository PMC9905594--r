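# Core domain types: concentration tables, sample metadata, configuration.
#
# A volatilome table is an ordinary tibble carrying one row per measurement
# (sample_id x time_point) with metadata columns followed by one numeric
# column per mass peak.  Peak columns are named "ms<m/z to 4 decimals>"
# (e.g. "ms31.0182") and kept in ascending m/z order.  Whether the table has
# been background-corrected is recorded in the "corrected" attribute:
# uncorrected tables must be non-negative, corrected tables may hold negative
# values (consumption below the growth-medium baseline).

#' @keywords internal
vol_meta_cols <- c("sample_id", "time_point", "role", "species", "strain",
                   "replicate")

#' @keywords internal
vol_roles <- c("empty_blank", "medium_blank", "fungal_pure", "bacterial_pure",
               "co_culture")

# roles for which species/strain must be empty
#' @keywords internal
vol_taxonless_roles <- c("empty_blank", "medium_blank", "bacterial_pure")

#' Mass-peak label helpers
#'
#' Mass peaks are labelled `"ms"` followed by the mass-to-charge ratio printed
#' to four decimals, e.g. `"ms31.0182"` for protonated formaldehyde.
#' `make_peak_label()` formats an m/z into a label and `peak_mz()` parses a
#' label back to its m/z (within 1e-4 Da by construction).
#'
#' @param mz Numeric vector of mass-to-charge ratios (Da), strictly positive.
#' @param label Character vector of peak labels.
#' @return `make_peak_label()` a character vector; `peak_mz()` a numeric
#'   vector of m/z values.
#' @examples
#' make_peak_label(31.01824)
#' peak_mz("ms31.0182")
#' @export
make_peak_label <- function(mz) {
  stopifnot(is.numeric(mz), all(is.finite(mz)), all(mz > 0))
  sprintf("ms%.4f", mz)
}

#' @rdname make_peak_label
#' @export
peak_mz <- function(label) {
  out <- suppressWarnings(as.numeric(sub("^ms", "", label)))
  if (anyNA(out) || any(out <= 0)) {
    abort(paste0("Invalid mass-peak label(s): ",
                 paste(label[is.na(out) | out <= 0], collapse = ", ")))
  }
  out
}

#' List the mass-peak columns of a volatilome table
#'
#' @param data A volatilome tibble.
#' @return Character vector of peak column names, in table order.
#' @export
peak_labels <- function(data) {
  grep("^ms[0-9]", names(data), value = TRUE)
}

#' Query or set the background-correction flag
#'
#' @param data A volatilome tibble.
#' @return `is_corrected()` returns a single logical; `mark_corrected()`
#'   returns `data` with the flag set.
#' @export
is_corrected <- function(data) {
  isTRUE(attr(data, "corrected"))
}

#' @rdname is_corrected
#' @param value Logical flag.
#' @export
mark_corrected <- function(data, value = TRUE) {
  attr(data, "corrected") <- isTRUE(value)
  data
}

#' Construct and validate a volatilome table
#'
#' Binds measurement metadata to concentration values, orders peak columns by
#' ascending m/z, sets the correction flag, and validates all structural
#' invariants (see `validate_volatilome()`).
#'
#' @param data Tibble with the metadata columns `sample_id`, `time_point`,
#'   `role`, `species`, `strain`, `replicate` followed by peak columns.
#' @param corrected Logical; has background correction been applied?
#'   Defaults to the flag already on `data`, or `FALSE`.
#' @return A validated volatilome tibble.
#' @export
as_volatilome <- function(data, corrected = is_corrected(data)) {
  data <- as_tibble(data)
  peaks <- peak_labels(data)
  extra <- setdiff(names(data), c(vol_meta_cols, peaks))
  data <- data[, c(vol_meta_cols, extra, peaks[order(peak_mz(peaks))])]
  data <- mark_corrected(data, corrected)
  validate_volatilome(data)
}

#' Validate the invariants of a volatilome table
#'
#' Checks that metadata columns are present, `(sample_id, time_point)` keys
#' are unique, roles are known, species/strain are empty exactly for blanks
#' and the bacterial pure culture, peak labels are unique, and all
#' concentrations are finite (non-negative unless corrected).
#'
#' @param data A volatilome tibble.
#' @return `data`, invisibly validated (returned unchanged).
#' @export
validate_volatilome <- function(data) {
  missing_meta <- setdiff(vol_meta_cols, names(data))
  if (length(missing_meta)) {
    abort(paste0("Missing metadata column(s): ",
                 paste(missing_meta, collapse = ", ")))
  }
  peaks <- peak_labels(data)
  if (anyDuplicated(peaks)) {
    abort("Duplicate mass-peak columns.")
  }
  key <- paste(data$sample_id, data$time_point)
  if (anyDuplicated(key)) {
    abort(paste0("Duplicate (sample_id, time_point) key: ",
                 key[anyDuplicated(key)][1]))
  }
  bad_role <- setdiff(unique(data$role), vol_roles)
  if (length(bad_role)) {
    abort(paste0("Unknown role(s): ", paste(bad_role, collapse = ", ")))
  }
  taxonless <- data$role %in% vol_taxonless_roles
  has_taxon <- !is.na(data$species) & nzchar(data$species)
  if (any(taxonless & has_taxon) || any(!taxonless & !has_taxon)) {
    abort("species/strain must be empty exactly for blanks and the bacterial pure culture.")
  }
  if (length(peaks)) {
    vals <- as.matrix(data[peaks])
    if (!all(is.finite(vals))) {
      abort("Non-finite concentration values present.")
    }
    if (!is_corrected(data) && any(vals < 0)) {
      abort("Negative concentrations are only permitted after background correction.")
    }
  }
  invisible(data)
}

#' Read a concentration table and its sample metadata
#'
#' The concentration file holds one header row of peak labels with key
#' columns `sample_id` and `time_point`; the metadata file holds one record
#' per `(sample_id, time_point)` with role, species, strain and replicate
#' (plus an optional `corrected` flag column, defaulting to `FALSE`).
#' Unknown metadata columns are preserved.
#'
#' @param path Path to the concentration CSV.
#' @param metadata_path Path to the metadata CSV.
#' @return A validated volatilome tibble.
#' @export
read_concentration_table <- function(path, metadata_path) {
  if (!file.exists(path)) abort(paste0("No such file: ", path))
  if (!file.exists(metadata_path)) abort(paste0("No such file: ", metadata_path))
  values <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  meta <- readr::read_csv(metadata_path, show_col_types = FALSE, progress = FALSE)
  peaks <- peak_labels(values)
  for (p in peaks) {
    col <- values[[p]]
    if (nrow(values) == 0) {
      values[[p]] <- numeric(0)
    } else if (!is.numeric(col)) {
      bad <- which(is.na(suppressWarnings(as.numeric(col))) & !is.na(col))[1]
      abort(paste0("Non-numeric concentration at row ", bad, ", column ", p))
    }
  }
  corrected <- FALSE
  if ("corrected" %in% names(meta)) {
    corrected <- isTRUE(all(meta$corrected))
    meta$corrected <- NULL
  }
  vkey <- paste(values$sample_id, values$time_point)
  mkey <- paste(meta$sample_id, meta$time_point)
  if (anyDuplicated(mkey)) {
    abort(paste0("Duplicate metadata record for key: ", mkey[duplicated(mkey)][1]))
  }
  missing <- setdiff(vkey, mkey)
  if (length(missing)) {
    abort(paste0("Metadata lacks record(s) for key(s): ",
                 paste(head(missing, 3), collapse = "; ")))
  }
  joined <- left_join(meta[mkey %in% vkey, , drop = FALSE], values,
                      by = c("sample_id", "time_point"))
  joined$species <- as.character(joined$species)
  joined$strain <- as.character(joined$strain)
  as_volatilome(joined, corrected = corrected)
}

#' Write a concentration table and its metadata
#'
#' Peak columns are written in ascending m/z order so output files are
#' byte-stable across runs; full floating precision is kept. Metadata
#' (including the correction flag) goes to a companion CSV.
#'
#' @param data A volatilome tibble.
#' @param path Output path for the concentration CSV.
#' @param metadata_path Output path for the metadata CSV; defaults to
#'   `path` with a `_metadata.csv` suffix.
#' @return `path`, invisibly.
#' @export
write_concentration_table <- function(data, path,
                                      metadata_path = sub("\\.csv$", "_metadata.csv", path)) {
  validate_volatilome(data)
  peaks <- peak_labels(data)
  peaks <- peaks[order(peak_mz(peaks))]
  values <- data[, c("sample_id", "time_point", peaks)]
  meta <- data[, setdiff(names(data), peaks)]
  meta$corrected <- is_corrected(data)
  readr::write_csv(values, path, progress = FALSE)
  readr::write_csv(meta, metadata_path, progress = FALSE)
  invisible(path)
}

#' Bin a concentration into the standard display bins
#'
#' Concentrations (ppbV) are grouped into eight ordinal bins used for
#' heat-map display: 0 below 0.2; 1 in \[0.2, 0.5); 2 in \[0.5, 1);
#' 3 in \[1, 5); 4 in \[5, 10); 5 in \[10, 20); 6 in \[20, 50); 7 at or
#' above 50.  Boundaries are closed on the left.
#'
#' @param value Numeric vector of concentrations (ppbV); must be finite.
#' @return Integer vector of bins in 0..7.
#' @examples
#' bin_concentration(c(0, 0.3, 75))
#' @export
bin_concentration <- function(value) {
  if (!is.numeric(value) || !all(is.finite(value))) {
    abort("Concentrations must be finite numbers.")
  }
  findInterval(value, c(0.2, 0.5, 1, 5, 10, 20, 50))
}

#' Analysis configuration
#'
#' Bundles the tunable analysis parameters: the detection-threshold scan
#' (ppbV), significance level, RNG seed, LDA training fraction, the
#' standardized-residual cutoff for outlier flagging, the minimum variance
#' share for a linear discriminant to be interpreted, and the fold-change
#' bound for calling "strong" production/consumption.
#'
#' @param thresholds Strictly increasing non-negative detection limits (ppbV).
#' @param alpha Significance level in (0, 1).
#' @param seed Integer seed used by every stochastic step.
#' @param train_fraction LDA training proportion in (0, 1).
#' @param outlier_z Standardized-residual cutoff for outlier flagging.
#' @param min_ld_variance Minimum variance share of an interpreted LD.
#' @param strong_fold Fold-change bound for strong production/consumption.
#' @return A list of class `analysis_config`.
#' @export
analysis_config <- function(thresholds = c(0, 0.05, 0.2, 0.5, 1, 5, 10, 20),
                            alpha = 0.05,
                            seed = 1L,
                            train_fraction = 0.7,
                            outlier_z = 2,
                            min_ld_variance = 0.1,
                            strong_fold = 2) {
  stopifnot(is.numeric(thresholds), all(thresholds >= 0),
            all(diff(thresholds) > 0),
            alpha > 0, alpha < 1,
            train_fraction > 0, train_fraction < 1,
            outlier_z > 0, min_ld_variance >= 0, strong_fold > 1)
  structure(list(thresholds = thresholds, alpha = alpha,
                 seed = as.integer(seed), train_fraction = train_fraction,
                 outlier_z = outlier_z, min_ld_variance = min_ld_variance,
                 strong_fold = strong_fold),
            class = "analysis_config")
}

#' Read/write an analysis configuration as a flat key-value file
#'
#' @param path File path.
#' @return `read_analysis_config()` an `analysis_config`;
#'   `write_analysis_config()` the path, invisibly.
#' @export
write_analysis_config <- function(config, path) {
  stopifnot(inherits(config, "analysis_config"))
  lines <- vapply(names(config), function(k) {
    paste0(k, ": ", paste(config[[k]], collapse = " "))
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_analysis_config
#' @param config An `analysis_config` object.
#' @export
read_analysis_config <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  kv <- strsplit(lines, ":", fixed = TRUE)
  vals <- lapply(kv, function(x) as.numeric(strsplit(trimws(x[2]), " +")[[1]]))
  names(vals) <- vapply(kv, function(x) trimws(x[1]), character(1))
  do.call(analysis_config, vals)
}
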