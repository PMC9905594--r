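# Blank screen, autocorrelation screen, thresholds, time stability.

blankish <- function(values_blank, values_sample, corrected = TRUE) {
  # corrected = TRUE by default so toy columns may hold negative values
  nb <- length(values_blank); ns <- length(values_sample)
  as_volatilome(corrected = corrected, tibble::tibble(
    sample_id = c(sprintf("e%d", seq_len(nb)), sprintf("f%d", seq_len(ns))),
    time_point = 1L,
    role = rep(c("empty_blank", "fungal_pure"), c(nb, ns)),
    species = rep(c(NA, "species_A"), c(nb, ns)),
    strain = rep(c(NA, "species_A_s1"), c(nb, ns)),
    replicate = c(seq_len(nb), seq_len(ns)),
    ms50.0000 = c(values_blank, values_sample),
    ms60.0000 = rep(1, nb + ns)))
}

test_that("blank screen removes null peaks and keeps separated ones", {
  set.seed(1)
  same <- rnorm(12, 5, 0.5)
  x <- blankish(same[1:6], same[7:12])
  x$ms60.0000 <- c(rnorm(6, 0, 0.01), rnorm(6, 10, 0.01))
  res <- filter_blank_peaks(x, alpha = 0.05)
  expect_false("ms50.0000" %in% peak_labels(res$data))   # identical dists
  expect_true("ms60.0000" %in% peak_labels(res$data))    # mean 10 vs 0
  expect_equal(res$report$n_input, 2)
  expect_equal(res$report$n_retained, 1)
  expect_error(filter_blank_peaks(x[x$role != "empty_blank", ]),
               "empty_blank")
})

test_that("blank screen removes most inert peaks on synthetic data", {
  # 20 inert among 100; expected removal >= 18/20 on average
  removed <- vapply(1:8, function(s) {
    d <- simulation_design(n_species = 1, strains_per_species = 2,
                           n_peaks = 100, frac_medium = 0.2,
                           frac_bacterial = 0.25, frac_fungal_produced = 0.15,
                           frac_fungal_consumed = 0.10,
                           frac_isotopologue = 0.10, seed = s)
    ex <- simulate_experiment(d)
    inert <- ex$truth$peaks$label[ex$truth$peaks$role == "inert_noise"]
    res <- filter_blank_peaks(ex$concentrations)
    sum(inert %in% res$report$removed_blank)
  }, numeric(1))
  expect_gte(mean(removed), 18)
})

test_that("autocorrelation screen keeps the lightest member of each group", {
  set.seed(2)
  a <- rnorm(12, 10, 2)
  x <- blankish(a[1:6], a[7:12])
  x$ms60.0000 <- 0.21 * x$ms50.0000          # r = 1, heavier -> removed
  x$ms70.0000 <- rnorm(12)                   # independent -> kept
  x <- as_volatilome(x)
  res <- filter_autocorrelated_peaks(x, r_cut = 0.99)
  expect_setequal(peak_labels(res$data), c("ms50.0000", "ms70.0000"))
  expect_equal(res$report$removed_autocorrelated$kept, "ms50.0000")
  expect_equal(res$report$removed_autocorrelated$removed, "ms60.0000")
  expect_equal(res$report$n_input - res$report$n_retained, 1)
})

test_that("correlation chains collapse transitively to one kept peak", {
  set.seed(3)
  a <- rnorm(12, 10, 2)
  x <- blankish(a[1:6], a[7:12])
  x$ms60.0000 <- 2 * x$ms50.0000
  x$ms70.0000 <- 3 * x$ms60.0000
  x <- as_volatilome(x)
  res <- filter_autocorrelated_peaks(x)
  expect_equal(peak_labels(res$data), "ms50.0000")
})

test_that("constant columns are treated as uncorrelated with a warning", {
  set.seed(4)
  a <- rnorm(12, 10, 2)
  x <- blankish(a[1:6], a[7:12])   # ms60 constant at 1
  expect_warning(res <- filter_autocorrelated_peaks(x), "Constant")
  expect_setequal(peak_labels(res$data), c("ms50.0000", "ms60.0000"))
})

test_that("synthetic isotopologues are removed and their parents kept", {
  ex <- shared_experiment()
  res <- suppressWarnings(filter_autocorrelated_peaks(ex$concentrations))
  iso <- ex$truth$peaks[ex$truth$peaks$role == "isotopologue", ]
  expect_true(all(!iso$label %in% peak_labels(res$data)))
  expect_true(all(iso$parent %in% peak_labels(res$data)))
})

test_that("thresholding zeroes magnitudes below the limit, symmetrically", {
  x <- blankish(c(0.1, 0.25, 3, 0.15, 1, 2), c(0.19, 0.21, 5, 1, 2, 3))
  x0 <- apply_threshold(x, 0)
  expect_equal(x0, x)                                     # identity at 0
  x2 <- apply_threshold(x, 0.2)
  expect_equal(x2$ms50.0000[c(1, 4)], c(0, 0))
  expect_equal(x2$ms50.0000[3], 3)
  # corrected values: |value| rule preserves large consumption
  xc <- blankish(rep(1, 3), rep(1, 3))
  xc$ms50.0000 <- c(-0.1, -5, 0.1, 5, 0.3, -0.3)
  out <- apply_threshold(xc, 0.2)
  expect_equal(out$ms50.0000, c(0, -5, 0, 5, 0.3, -0.3))
  expect_true(is_corrected(out))
  expect_error(apply_threshold(x, -1), "non-negative")
})

test_that("thresholding is idempotent and monotone in the threshold", {
  ex <- shared_experiment()
  x <- ex$corrected
  t1 <- apply_threshold(x, 0.2)
  expect_equal(apply_threshold(t1, 0.2), t1)
  t2 <- apply_threshold(x, 1)
  z1 <- as.matrix(t1[peak_labels(t1)]) == 0
  z2 <- as.matrix(t2[peak_labels(t2)]) == 0
  expect_true(all(z2 >= z1))  # zeros at 0.2 stay zero at 1
})

test_that("time-stability screen measures trend strength correctly", {
  base <- blankish(rep(2, 6), rep(2, 6))
  base$time_point <- rep(1:3, 4)
  base$sample_id <- rep(c("e1", "e2", "f1", "f2"), each = 3)
  base$replicate <- rep(c(1L, 2L, 1L, 2L), each = 3)
  x <- as_volatilome(base)
  x$ms60.0000 <- 2 * x$time_point            # perfect trend
  ts <- analyze_time_stability(x)
  flat <- ts[ts$peak == "ms50.0000", ]
  expect_equal(flat$pct_variance, 0)
  expect_gte(flat$p_value, 0.05)
  perfect <- ts[ts$peak == "ms60.0000", ]
  expect_equal(perfect$pct_variance, 100)
  expect_equal(perfect$slope, 2)
  one_tp <- x[x$time_point == 1, ]
  expect_error(analyze_time_stability(one_tp), "two time points")
})

test_that("planted medium time trends are recovered at alpha = 0.05", {
  recall <- vapply(1:8, function(s) {
    d <- simulation_design(n_species = 1, strains_per_species = 2,
                           n_peaks = 80, seed = s)
    ex <- simulate_experiment(d)
    trending <- ex$truth$peaks$label[ex$truth$peaks$trending]
    ts <- analyze_time_stability(ex$concentrations)
    mean(ts$p_value[match(trending, ts$peak)] < 0.05)
  }, numeric(1))
  expect_gte(mean(recall), 0.8)
})
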