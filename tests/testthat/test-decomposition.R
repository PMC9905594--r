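# Source-apportionment models 1-3, residual outliers, coefficient
# correlations.

toy_set <- function(B, FF, C, strain = "species_A_s1") {
  n <- length(B)
  dat <- tibble::tibble(peak = sprintf("ms%.4f", 50 + seq_len(n)),
                        F = FF, B = B, C = C)
  structure(list(strain = strain, data = dat,
                 s_bact_only = dat$peak[dat$B > 0 & dat$F == 0],
                 s_fungal = dat$peak[dat$F != 0]),
            class = "strain_volatilome")
}

test_that("strain sets hold per-peak means and the model subsets", {
  ex <- shared_experiment()
  st <- ex$truth$coefficients$strain[1]
  set <- build_strain_set(ex$corrected, st)
  peaks <- peak_labels(ex$corrected)
  expect_equal(set$data$peak, peaks)
  rows <- ex$corrected$role == "fungal_pure" & ex$corrected$strain == st
  expect_equal(set$data$F,
               unname(colMeans(as.matrix(ex$corrected[rows, peaks]))))
  expect_true(all(set$s_bact_only %in% peaks))
  expect_length(intersect(set$s_bact_only, set$s_fungal), 0)
  # subset semantics: B > 0 and F exactly 0
  sub <- set$data[set$data$peak %in% set$s_bact_only, ]
  expect_true(all(sub$B > 0 & sub$F == 0))
  expect_error(build_strain_set(ex$corrected, "no_such_strain"),
               "No fungal pure rows")
})

test_that("bacteria-only subsets align with ground-truth roles", {
  ex <- shared_experiment()
  st <- ex$truth$coefficients$strain[2]
  set <- build_strain_set(ex$corrected, st)
  roles <- setNames(ex$truth$peaks$role, ex$truth$peaks$label)
  # peaks the fungus never touches are bacterial or medium/inert; none are
  # fungal-produced or consumed
  expect_false(any(roles[set$s_bact_only] %in%
                     c("fungal_produced", "fungal_consumed")))
  # the operational rule (corrected fungal mean exactly zero) keeps a peak
  # only when all its fungal cells test null, so with per-cell alpha = 0.05
  # about 0.95^12 ~ 54% of truly untouched peaks qualify
  bact_peaks <- ex$truth$peaks$label[
    ex$truth$peaks$role == "bacterial_produced" & !ex$truth$peaks$regulated]
  expect_gte(mean(bact_peaks %in% set$s_bact_only), 0.35)
})

test_that("noise-free additive toys are fitted exactly", {
  set.seed(10)
  B <- c(rexp(4, 1 / 5), 0, 0, 0)
  FF <- c(0, 0, 0, 0, 2, 3, 4)
  C <- 0.5 * B + 1.0 * FF
  set <- toy_set(B, FF, C)
  m1 <- fit_model1(set)
  expect_equal(coef(m1$lm)[["B"]], 0.5, tolerance = 1e-10)
  expect_equal(coef(m1$lm)[["F"]], 1.0, tolerance = 1e-10)
  expect_equal(coef(m1$lm)[["(Intercept)"]], 0, tolerance = 1e-10)
  expect_equal(m1$adj_r2, 1, tolerance = 1e-10)

  m2 <- fit_model2(set)
  expect_equal(coef(m2$lm)[["B"]], 0.5, tolerance = 1e-10)
  expect_equal(m2$n_vocs, 4)

  m3 <- fit_model3(set, m2)
  expect_equal(coef(m3$lm)[["F"]], 1.0, tolerance = 1e-10)
  expect_equal(m3$n_vocs, 3)
})

test_that("C = B with orthogonal F gives a = 1, b = 0", {
  B <- c(1, 2, 3, 4, 5, 6)
  FF <- c(1, -1, 1, -1, 1, -1) - mean(c(1, -1))  # orthogonal to B? enforce:
  FF <- residuals(lm(FF ~ B))
  set <- toy_set(B, FF, B)
  m1 <- fit_model1(set)
  expect_equal(coef(m1$lm)[["B"]], 1, tolerance = 1e-8)
  expect_equal(coef(m1$lm)[["F"]], 0, tolerance = 1e-8)
})

test_that("all three fits reproduce the normal-equations oracle to 1e-8", {
  set.seed(11)
  for (rep in 1:5) {
    n <- sample(10:50, 1)
    B <- rexp(n, 1 / 3)
    FF <- rnorm(n, 0, 2)
    zero_f <- sample(n, floor(n / 3))
    FF[zero_f] <- 0
    C <- 0.4 * B + 0.9 * FF + rnorm(n, 0, 0.3)
    set <- toy_set(B, FF, C)

    m1 <- fit_model1(set)
    o1 <- ols_oracle(cbind(1, B, FF), C)
    expect_equal(unname(coef(m1$lm)), unname(o1), tolerance = 1e-8)

    m2 <- fit_model2(set)
    sub <- set$data$peak %in% set$s_bact_only
    o2 <- ols_oracle(cbind(1, B[sub]), C[sub])
    expect_equal(unname(coef(m2$lm)), unname(o2), tolerance = 1e-8)

    m3 <- fit_model3(set, m2)
    fsub <- set$data$peak %in% set$s_fungal
    R <- C[fsub] - o2[2] * B[fsub]
    o3 <- ols_oracle(cbind(1, FF[fsub]), R)
    expect_equal(unname(coef(m3$lm)), unname(o3), tolerance = 1e-8)
  }
})

test_that("collinear predictors and small subsets are handled explicitly", {
  B <- 1:6
  set_coll <- toy_set(B, 2 * B, 3 * B)
  expect_error(fit_model1(set_coll), "condition number")
  set_small <- toy_set(c(0, 0, 0, 0, 1, 2), c(1, 2, 3, 4, 5, 6), rnorm(6))
  m2 <- fit_model2(set_small)
  expect_equal(m2$status, "skipped_small_subset")
  expect_error(fit_model3(set_small, m2), "model 2")
})

test_that("unrelated predictors in model 2 test as insignificant", {
  # permutation oracle for the p-value of a null slope
  set.seed(12)
  n <- 30
  B <- rexp(n, 1 / 3)
  C <- rnorm(n, 5, 1)          # independent of B
  set <- toy_set(B, rep(0, n), C)
  m2 <- fit_model2(set)
  p_fit <- m2$coefficients$p_value[m2$coefficients$term == "B"]
  perm <- replicate(400, {
    cp <- cor(sample(B), C)
    abs(cp)
  })
  p_perm <- mean(perm >= abs(cor(B, C)))
  expect_gt(p_fit, 0.05)
  expect_lt(abs(p_fit - p_perm), 0.15)
})

test_that("planted coefficients are recovered through the full pipeline", {
  res <- vapply(1:6, function(s) {
    ex <- simulate_corrected(recovery_design(s, a_true = 0.3, b_true = 0.5))
    set <- build_strain_set(ex$corrected, ex$truth$coefficients$strain[1])
    m1 <- fit_model1(set); m2 <- fit_model2(set); m3 <- fit_model3(set, m2)
    c(tidy(m1)$estimate[tidy(m1)$term == "B"],
      tidy(m2)$estimate[tidy(m2)$term == "B"],
      tidy(m3)$estimate[tidy(m3)$term == "F"])
  }, numeric(3))
  expect_equal(mean(res[1, ]), 0.3, tolerance = 0.05)
  expect_equal(mean(res[2, ]), 0.3, tolerance = 0.05)
  expect_equal(mean(res[3, ]), 0.5, tolerance = 0.1)
})

test_that("model-3 and model-1 fungal coefficients agree across strains", {
  ex <- shared_experiment()
  fits <- fit_decomposition(ex$corrected)
  tab <- decomposition_table(fits)
  b1 <- tab$estimate[tab$model == 1 & tab$term == "F"]
  b3 <- tab$estimate[tab$model == 3 & tab$term == "F"]
  expect_gte(cor(b1, b3), 0.7)
})

test_that("recurrent residual outliers recover the planted regulated set", {
  hits <- lapply(1:5, function(s) {
    d <- simulation_design(n_species = 2, strains_per_species = 5,
                           n_peaks = 100, n_regulated = 5, seed = s)
    ex <- simulate_corrected(d)
    strains <- ex$truth$coefficients$strain
    m1 <- lapply(strains, function(st)
      fit_model1(build_strain_set(ex$corrected, st)))
    rep <- detect_regulated_vocs(m1, outlier_z = 2)
    truth_reg <- ex$truth$peaks$label[ex$truth$peaks$regulated]
    # direction of planted deviations is recovered too
    det <- rep[rep$peak %in% truth_reg, ]
    fac <- ex$truth$peaks$deviation_factor[match(det$peak,
                                                 ex$truth$peaks$label)]
    list(recall = mean(truth_reg %in% rep$peak),
         fp = sum(!rep$peak %in% truth_reg),
         dir_ok = mean(ifelse(fac > 1, det$direction == "above",
                              det$direction == "below")))
  })
  expect_gte(mean(vapply(hits, `[[`, numeric(1), "recall")), 0.8)
  expect_lte(mean(vapply(hits, `[[`, numeric(1), "fp")), 2)
  expect_gte(mean(vapply(hits, `[[`, numeric(1), "dir_ok"), na.rm = TRUE),
             0.8)
})

test_that("all-zero residuals produce an empty regulated report", {
  B <- c(1, 2, 3, 4, 5, 6); FF <- c(0, 0, 0, 1, 2, 3)
  set <- toy_set(B, FF, 0.5 * B + FF)
  rep <- detect_regulated_vocs(list(fit_model1(set)), outlier_z = 2,
                               min_frequency = 1)
  expect_equal(nrow(rep), 0)
})

test_that("cross-model correlations behave on identical and real columns", {
  ident <- tibble::tibble(bacterial_m1 = 1:6 / 10, bacterial_m2 = 1:6 / 10,
                          fungal_m1 = c(6:1) / 5, fungal_m3 = c(6:1) / 5)
  cc <- coefficient_correlations(ident)
  expect_true(all(abs(cc$r - 1) < 1e-12))
  ex <- shared_experiment()
  fits <- fit_decomposition(ex$corrected)
  cc2 <- coefficient_correlations(fits)
  expect_equal(nrow(cc2), 4)
  r_bact <- cc2$r[cc2$pair == "bacterial_m1_vs_m2" & cc2$method == "pearson"]
  expect_gt(r_bact, 0.7)
})

test_that("tidiers expose coefficients, fit summaries and residuals", {
  B <- c(1, 2, 3, 4, 5, 6); FF <- c(0, 0, 0, 1, 2, 3)
  m1 <- fit_model1(toy_set(B, FF, 0.5 * B + FF + rnorm(6, 0, 0.01)))
  td <- tidy(m1)
  expect_setequal(td$term, c("(Intercept)", "B", "F"))
  gl <- glance(m1)
  expect_equal(gl$n_vocs, 6)
  au <- augment(m1)
  expect_equal(nrow(au), 6)
  expect_equal(mean(au$residual), 0, tolerance = 1e-10)
})
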