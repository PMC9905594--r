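# Nested growth ANOVA, effect sizes, pure-vs-co comparisons, correlations.

toy_growth <- function(n_species = 2, strains = 2, reps = 4,
                       species_eff = c(0, 3), co_eff = 0, sd = 0.3,
                       seed = 1) {
  set.seed(seed)
  grid <- tidyr::expand_grid(
    species = paste0("species_", LETTERS[seq_len(n_species)]),
    s = seq_len(strains), medium = c("PDA", "LcA"),
    mode = c("pure", "co"), replicate = seq_len(reps))
  grid$strain <- paste0(grid$species, "_s", grid$s)
  mu <- species_eff[match(grid$species, unique(grid$species))] + 6 +
    (grid$mode == "co") * co_eff
  tibble::tibble(strain = grid$strain, species = grid$species,
                 medium = grid$medium, mode = grid$mode,
                 replicate = grid$replicate,
                 rate = pmax(mu + rnorm(nrow(grid), 0, sd), 0.1))
}

test_that("effect sizes are sums-of-squares percentages that total 100", {
  es <- effect_sizes(c(A = 50, resid = 50))
  expect_equal(es$effect_pct, c(50, 50))
  set.seed(2)
  for (k in 1:5) {
    ss <- rexp(sample(3:8, 1))
    es <- effect_sizes(ss)
    expect_equal(sum(es$effect_pct), 100, tolerance = 1e-10)
  }
  expect_error(effect_sizes(c(A = 0, B = 0)), "positive")
})

test_that("the ANOVA reproduces a projection-matrix decomposition", {
  # oracle: sequential SS via explicit orthogonal projections
  rec <- toy_growth(seed = 3)
  tab <- fit_growth_anova(rec, reduce = FALSE)
  y <- rec$rate
  terms <- c("species", "medium", "mode", "species:strain",
             "species:medium", "species:mode",
             "species:medium:strain", "species:mode:strain")
  X_list <- lapply(seq_along(terms), function(i) {
    stats::model.matrix(stats::reformulate(terms[seq_len(i)]),
                        data = dplyr::mutate(rec, dplyr::across(
                          c(species, strain, medium, mode), factor)))
  })
  proj_ss <- function(X) {
    q <- qr(X)
    fitted <- qr.fitted(q, y)
    sum((fitted - mean(y))^2)
  }
  cum <- vapply(X_list, proj_ss, numeric(1))
  seq_ss <- diff(c(0, cum))
  got <- tab$sumsq[match(terms, tab$term)]
  expect_equal(unname(got), unname(seq_ss), tolerance = 1e-8)
  expect_equal(sum(tab$sumsq), sum((y - mean(y))^2), tolerance = 1e-8)
})

test_that("a planted species effect dominates the table", {
  rec <- toy_growth(species_eff = c(0, 3), co_eff = 0.2, seed = 4)
  tab <- fit_growth_anova(rec)
  expect_false(attr(tab, "degenerate"))
  biggest <- tab$term[which.max(tab$effect_pct)]
  expect_equal(biggest, "species")
  ov <- attr(tab, "overall")
  expect_gt(ov$adj_r2, 0.8)
})

test_that("constant rates are flagged as degenerate", {
  rec <- toy_growth(species_eff = c(0, 0), sd = 0, seed = 5)
  rec$rate <- 5
  tab <- fit_growth_anova(rec)
  expect_true(attr(tab, "degenerate"))
  expect_equal(sum(tab$sumsq), 0, tolerance = 1e-20)
})

test_that("missing design cells are reported by name", {
  rec <- toy_growth(seed = 6)
  rec <- rec[!(rec$species == "species_A" & rec$medium == "LcA"), ]
  expect_error(fit_growth_anova(rec), "species_A/LcA")
})

test_that("model reduction drops insignificant interactions only", {
  rec <- toy_growth(species_eff = c(0, 4), co_eff = 0, seed = 7)
  tab <- fit_growth_anova(rec, alpha = 0.05, reduce = TRUE)
  kept <- tab$term[tab$term != "Residuals"]
  expect_true("species" %in% kept)
  rows <- tab[tab$term != "Residuals", ]
  expect_true(all(rows$p_value < 0.05 |
                    vapply(rows$term, function(tm) {
                      any(vapply(setdiff(rows$term, tm), function(o)
                        all(strsplit(tm, ":")[[1]] %in%
                              strsplit(o, ":")[[1]]), logical(1)))
                    }, logical(1))))
})

test_that("pure-vs-co comparisons match the two-sample oracle", {
  rec <- tibble::tibble(
    strain = "species_A_s1", species = "species_A", medium = "PDA",
    mode = rep(c("pure", "co"), each = 3), replicate = rep(1:3, 2),
    rate = c(8.0, 8.1, 8.2, 9.0, 9.1, 9.2))
  cmp <- compare_growth(rec)
  expect_equal(cmp$difference, 1, tolerance = 1e-12)
  expect_equal(cmp$direction, "faster")
  tt <- t.test(c(9.0, 9.1, 9.2), c(8.0, 8.1, 8.2))
  expect_equal(cmp$p_value, tt$p.value, tolerance = 1e-10)

  rec_same <- rec
  rec_same$rate <- rep(c(8.0, 8.1, 8.2), 2)
  cmp2 <- compare_growth(rec_same)
  expect_equal(cmp2$difference, 0)
  expect_equal(cmp2$direction, "ns")
})

test_that("planted co-culture effects are recovered when large", {
  ok <- vapply(1:8, function(s) {
    rec <- toy_growth(species_eff = c(0, 2), co_eff = 1.2, sd = 0.3,
                      reps = 5, seed = s)
    cmp <- compare_growth(rec)
    all(cmp$direction == "faster")
  }, logical(1))
  expect_gte(mean(ok), 0.9)
})

test_that("coefficient-distance-growth correlations behave", {
  ex <- shared_experiment()
  fits <- fit_decomposition(ex$corrected)
  lda <- train_lda(ex$corrected, "species_mode", seed = 1)
  dist <- suppressWarnings(centroid_distances(lda$model, ex$corrected))
  cmp <- compare_growth(ex$growth)
  tabcor <- correlate_with_volatilome(cmp, fits, dist)
  expect_setequal(unique(tabcor$target),
                  c("centroid_distance", "growth_difference"))
  expect_true(all(c("pearson", "spearman") %in% tabcor$method))
  # r is NA when a scenario degenerates (e.g. every growth difference ns)
  expect_true(all(abs(tabcor$r) <= 1 + 1e-12, na.rm = TRUE))
  raw <- tabcor[tabcor$scenario != "zeroed", ]
  expect_true(all(is.finite(raw$r)))

  # identical coefficient and distance columns give r = 1
  fake_fit <- fits[[1]]
  dist_fake <- tibble::tibble(
    strain = ex$truth$coefficients$strain,
    distance = NA_real_)
  tab <- decomposition_table(fits)
  a1 <- tab[tab$model == 1 & tab$term == "B", ]
  dist_fake$distance <- a1$estimate[match(dist_fake$strain, a1$strain)]
  t2 <- correlate_with_volatilome(cmp, fits, dist_fake)
  r_ident <- t2$r[t2$coefficient == "bacterial" & t2$model == 1 &
                    t2$target == "centroid_distance" &
                    t2$method == "pearson"]
  expect_equal(r_ident, 1, tolerance = 1e-12)
})
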