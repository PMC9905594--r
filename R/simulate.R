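# Ground-truthed synthetic co-cultivation experiments.
#
# The generator emulates the design of a fungal-bacterial co-plating study
# measured by PTR-ToF-MS: vials of growth medium only (the PDA null), empty
# vials, one bacterial pure culture, one fungal pure culture per strain, and
# one co-culture per strain, each measured in technical replicates across
# several time points.  The bacterium predominantly produces volatiles (and
# at higher levels than the fungi); the fungi both produce and consume.
# Co-cultures are additive in the two pure-culture signals scaled by latent
# "growth" coefficients a_true and b_true, except for a small planted set of
# interaction-regulated peaks that deviate multiplicatively from additivity.
# Isotopologue columns shadow a parent peak at a fixed ratio so the
# autocorrelation filter has something to remove.

#' Describe a synthetic co-cultivation experiment
#'
#' Defaults mirror the emulated study: 6 fungal species comprising 25
#' strains, 113 retained mass peaks, 3 technical replicates measured at 4
#' time points, 3 medium-blank and 3 empty-blank vials, and 5 growth-rate
#' replicates per strain x medium x cultivation mode.  Noise is
#' multiplicative log-normal plus a small additive floor (positive,
#' heteroscedastic, as PTR-ToF-MS intensities are).  Regulated peaks are
#' planted among the more abundant culture-produced peaks, as the recurrent
#' outliers reported for such co-cultures are all major compounds.
#'
#' @param n_species Number of fungal species.
#' @param strains_per_species Strains per species; scalar or vector of
#'   length `n_species`.
#' @param n_peaks Total number of mass-peak columns.
#' @param frac_medium,frac_bacterial,frac_fungal_produced,frac_fungal_consumed,frac_isotopologue
#'   Fractions of peaks per role; must sum to at most 1, the remainder is
#'   inert noise.
#' @param n_regulated Number of planted interaction-regulated peaks.
#' @param regulated_up,regulated_down Ranges for the multiplicative
#'   deviation factor of up-/down-regulated peaks.
#' @param replicates Technical replicates per culture.
#' @param time_points Measurement time points per vial.
#' @param blank_vials,empty_vials Medium-blank and empty-blank vials.
#' @param growth_replicates Growth-rate replicates per strain x medium x mode.
#' @param cons_range Range of the fraction of the medium level consumed by
#'   a fungal strain at a consumed peak.
#' @param bio_sigma Log-normal sd of the biological (vial-to-vial)
#'   variability multiplying each culture's contribution per peak.
#' @param noise_sigma Log-normal sd of the multiplicative measurement noise
#'   (technical-replicate scale for direct headspace injection).
#' @param noise_floor Scale (sd) of the additive half-normal noise floor (ppbV).
#' @param trend_fraction Fraction of medium-emitted peaks given a linear
#'   time trend.
#' @param trend_slope Trend slope per time-point step, relative to the
#'   peak's medium level.
#' @param a_range,b_range Ranges from which latent per-strain bacterial and
#'   fungal growth coefficients are drawn.
#' @param a_true,b_true Optional fixed coefficient values (recycled over
#'   strains), overriding the ranges.
#' @param seed Integer seed; all draws come from one seeded stream.
#' @return A list of class `simulation_design`.
#' @export
simulation_design <- function(n_species = 6,
                              strains_per_species = c(5, 5, 4, 3, 3, 5),
                              n_peaks = 113,
                              frac_medium = 0.22,
                              frac_bacterial = 0.28,
                              frac_fungal_produced = 0.14,
                              frac_fungal_consumed = 0.12,
                              frac_isotopologue = 0.10,
                              n_regulated = 5,
                              regulated_up = c(3, 5),
                              regulated_down = c(0.2, 1 / 3),
                              replicates = 3,
                              time_points = 4,
                              blank_vials = 3,
                              empty_vials = 3,
                              growth_replicates = 5,
                              cons_range = c(0.6, 0.95),
                              bio_sigma = 0.15,
                              noise_sigma = 0.03,
                              noise_floor = 0.02,
                              trend_fraction = 0.10,
                              trend_slope = 0.25,
                              a_range = c(0.3, 0.7),
                              b_range = c(0.3, 1.2),
                              a_true = NULL,
                              b_true = NULL,
                              seed = 1L) {
  if (length(strains_per_species) == 1) {
    strains_per_species <- rep(strains_per_species, n_species)
  }
  stopifnot(length(strains_per_species) == n_species,
            all(strains_per_species >= 1),
            n_peaks >= 2, replicates >= 1, time_points >= 1,
            blank_vials >= 1, empty_vials >= 1,
            noise_sigma >= 0, noise_floor >= 0)
  fracs <- c(frac_medium, frac_bacterial, frac_fungal_produced,
             frac_fungal_consumed, frac_isotopologue)
  if (any(fracs < 0) || sum(fracs) > 1 + 1e-12) {
    abort("Peak-role fractions must be non-negative and sum to at most 1.")
  }
  structure(list(n_species = n_species,
                 strains_per_species = strains_per_species,
                 n_peaks = n_peaks,
                 frac_medium = frac_medium,
                 frac_bacterial = frac_bacterial,
                 frac_fungal_produced = frac_fungal_produced,
                 frac_fungal_consumed = frac_fungal_consumed,
                 frac_isotopologue = frac_isotopologue,
                 n_regulated = n_regulated,
                 regulated_up = regulated_up,
                 regulated_down = regulated_down,
                 cons_range = cons_range,
                 replicates = replicates,
                 time_points = time_points,
                 blank_vials = blank_vials,
                 empty_vials = empty_vials,
                 growth_replicates = growth_replicates,
                 bio_sigma = bio_sigma,
                 noise_sigma = noise_sigma,
                 noise_floor = noise_floor,
                 trend_fraction = trend_fraction,
                 trend_slope = trend_slope,
                 a_range = a_range, b_range = b_range,
                 a_true = a_true, b_true = b_true,
                 seed = as.integer(seed)),
            class = "simulation_design")
}

#' Simulate a complete co-cultivation experiment
#'
#' Generates an uncorrected (non-negative) concentration table, daily radial
#' growth-rate records, and the ground truth behind both.  Expected
#' concentrations before noise: blanks carry the medium emission; the
#' bacterial pure culture adds its production; fungal pure cultures add
#' production and subtract consumption (floored at zero); co-cultures carry
#' medium plus `a_true` times the bacterial signal plus `b_true` times the
#' fungal signal, with regulated peaks' culture contribution multiplied by
#' their deviation factor.  Isotopologue columns equal their parent column
#' times a fixed ratio plus tiny noise.
#'
#' @param design A `simulation_design`.
#' @return A list of class `vol_experiment` with elements `concentrations`
#'   (volatilome tibble), `growth` (growth-record tibble) and `truth`
#'   (a `ground_truth` list; see [truth_report()]).
#' @export
simulate_experiment <- function(design) {
  stopifnot(inherits(design, "simulation_design"))
  d <- design
  set.seed(d$seed)

  species <- paste0("species_", LETTERS[seq_len(d$n_species)])
  strains <- unlist(lapply(seq_len(d$n_species), function(i) {
    paste0(species[i], "_s", seq_len(d$strains_per_species[i]))
  }))
  strain_species <- rep(species, d$strains_per_species)
  n_strains <- length(strains)

  ## ---- peak roles and base levels ----
  n <- d$n_peaks
  n_iso <- floor(d$frac_isotopologue * n)
  n_med <- floor(d$frac_medium * n)
  n_bac <- floor(d$frac_bacterial * n)
  n_fpr <- floor(d$frac_fungal_produced * n)
  n_fco <- floor(d$frac_fungal_consumed * n)
  n_inert <- n - n_iso - n_med - n_bac - n_fpr - n_fco
  roles <- c(rep("medium_emitted", n_med), rep("bacterial_produced", n_bac),
             rep("fungal_produced", n_fpr), rep("fungal_consumed", n_fco),
             rep("inert_noise", n_inert), rep("isotopologue", n_iso))

  mz <- numeric(0)
  while (length(unique(sprintf("%.4f", mz))) < n - n_iso) {
    mz <- sort(runif(n - n_iso, 30, 250))
  }

  med_level <- numeric(n)
  med_level[roles == "medium_emitted"] <- rlnorm(n_med, log(1.5), 1.2)
  med_level[roles == "fungal_consumed"] <- rlnorm(n_fco, log(4), 0.8)
  bact_level <- numeric(n)
  bact_level[roles == "bacterial_produced"] <- rlnorm(n_bac, log(8), 1.0)
  fung_base <- numeric(n)
  fung_base[roles == "fungal_produced"] <- rlnorm(n_fpr, log(0.6), 0.8)

  trending <- rep(FALSE, n)
  med_idx <- which(roles == "medium_emitted")
  n_trend <- round(d$trend_fraction * length(med_idx))
  if (n_trend > 0) trending[sample(med_idx, n_trend)] <- TRUE
  trend_slope <- ifelse(trending, d$trend_slope * med_level, 0)

  # isotopologue parents: heavier by one neutron, sampled among stable
  # signal peaks (trending peaks mirror each other and are filtered as a
  # correlated group of their own)
  parent_pool <- which(roles[seq_len(n - n_iso)] != "inert_noise" &
                         !trending[seq_len(n - n_iso)])
  parents <- if (n_iso) sample(parent_pool, n_iso) else integer(0)
  mz <- c(mz, mz[parents] + 1.00336)
  labels <- make_peak_label(mz)
  parent_label <- rep(NA_character_, n)
  if (n_iso) parent_label[(n - n_iso + 1):n] <- labels[parents]
  iso_ratio <- rep(NA_real_, n)
  if (n_iso) iso_ratio[(n - n_iso + 1):n] <- runif(n_iso, 0.01, 0.08)

  # Regulated peaks sit among the bacterially produced majors (recurrent
  # co-culture outliers are major compounds), with up-regulation planted on
  # mid-abundance peaks and down-regulation on more abundant ones so both
  # directions deviate from additivity by comparable absolute amounts.
  pick <- function(x, k) x[sample.int(length(x), min(k, length(x)))]
  produced <- which(roles == "bacterial_produced")
  if (!length(produced)) produced <- which(roles == "fungal_produced")
  n_reg <- min(d$n_regulated, length(produced))
  reg_up_idx <- reg_dn_idx <- integer(0)
  if (n_reg) {
    n_up <- sum(runif(n_reg) < 0.5)
    lev <- bact_level + fung_base
    qs <- quantile(lev[produced], c(0.4, 0.65, 0.7, 0.95))
    pool_up <- produced[lev[produced] >= qs[1] & lev[produced] <= qs[2]]
    pool_dn <- produced[lev[produced] >= qs[3] & lev[produced] <= qs[4]]
    reg_up_idx <- pick(pool_up, n_up)
    reg_dn_idx <- pick(pool_dn, n_reg - n_up)
    short <- n_reg - length(reg_up_idx) - length(reg_dn_idx)
    if (short > 0) {
      extra <- pick(setdiff(produced, c(reg_up_idx, reg_dn_idx)), short)
      reg_up_idx <- c(reg_up_idx, extra)
    }
  }
  reg_idx <- c(reg_up_idx, reg_dn_idx)
  regulated <- seq_len(n) %in% reg_idx
  dev_factor <- rep(1, n)
  dev_factor[reg_up_idx] <- runif(length(reg_up_idx), d$regulated_up[1],
                                  d$regulated_up[2])
  dev_factor[reg_dn_idx] <- runif(length(reg_dn_idx), d$regulated_down[1],
                                  d$regulated_down[2])

  ## ---- latent strain coefficients and fungal signals ----
  a_true <- if (is.null(d$a_true)) runif(n_strains, d$a_range[1], d$a_range[2])
            else rep_len(d$a_true, n_strains)
  b_true <- if (is.null(d$b_true)) runif(n_strains, d$b_range[1], d$b_range[2])
            else rep_len(d$b_true, n_strains)

  # per-strain fungal signal: production (strain-modulated) minus consumption
  prod_mult <- matrix(exp(rnorm(n_strains * n, 0, 0.3)), n_strains, n)
  cons_frac <- matrix(runif(n_strains * n, d$cons_range[1], d$cons_range[2]),
                      n_strains, n)
  fung_signal <- prod_mult * rep(fung_base, each = n_strains)
  fco <- roles == "fungal_consumed"
  fung_signal[, fco] <- -cons_frac[, fco, drop = FALSE] *
    rep(med_level[fco], each = n_strains)

  ## ---- measurement rows ----
  tps <- seq_len(d$time_points)
  row_block <- function(ids, role, sp, st, rep_no) {
    tibble(sample_id = rep(ids, each = d$time_points),
           time_point = rep(tps, length(ids)),
           role = role,
           species = sp, strain = st,
           replicate = rep(rep_no, each = d$time_points))
  }
  meta <- bind_rows(
    row_block(sprintf("empty_v%d", seq_len(d$empty_vials)), "empty_blank",
              NA_character_, NA_character_, seq_len(d$empty_vials)),
    row_block(sprintf("pda_v%d", seq_len(d$blank_vials)), "medium_blank",
              NA_character_, NA_character_, seq_len(d$blank_vials)),
    row_block(sprintf("bact_r%d", seq_len(d$replicates)), "bacterial_pure",
              NA_character_, NA_character_, seq_len(d$replicates)),
    bind_rows(lapply(seq_len(n_strains), function(s) {
      bind_rows(
        row_block(sprintf("%s_pure_r%d", strains[s], seq_len(d$replicates)),
                  "fungal_pure", strain_species[s], strains[s],
                  seq_len(d$replicates)),
        row_block(sprintf("%s_co_r%d", strains[s], seq_len(d$replicates)),
                  "co_culture", strain_species[s], strains[s],
                  seq_len(d$replicates)))
    }))
  )
  n_rows <- nrow(meta)

  # expected concentration per row x peak
  t_centered <- meta$time_point - (d$time_points + 1) / 2
  med_part <- pmax(outer(rep(1, n_rows), med_level) +
                     outer(t_centered, trend_slope), 0)
  med_part[meta$role == "empty_blank", ] <- 0
  expected <- med_part
  # biological (vial-to-vial) variability multiplies the culture
  # contribution, not the medium emission, so production ratios differ
  # between vials and peak columns are not mutually proportional
  bio <- function(rows) {
    # one multiplier per vial x peak, shared by the vial's time points
    ids <- meta$sample_id[rows]
    u <- unique(ids)
    m <- matrix(exp(rnorm(length(u) * n, 0, d$bio_sigma)), length(u), n)
    m[match(ids, u), , drop = FALSE]
  }
  bac_rows <- which(meta$role == "bacterial_pure")
  expected[bac_rows, ] <- expected[bac_rows, , drop = FALSE] +
    rep(bact_level, each = length(bac_rows)) * bio(bac_rows)
  s_of_row <- match(meta$strain, strains)
  fp <- which(meta$role == "fungal_pure")
  expected[fp, ] <- pmax(
    expected[fp, , drop = FALSE] +
      fung_signal[s_of_row[fp], , drop = FALSE] * bio(fp), 0)
  cc <- which(meta$role == "co_culture")
  contrib <- a_true[s_of_row[cc]] %o% bact_level +
    b_true[s_of_row[cc]] * fung_signal[s_of_row[cc], , drop = FALSE]
  contrib <- contrib * rep(dev_factor, each = length(cc)) * bio(cc)
  expected[cc, ] <- pmax(expected[cc, , drop = FALSE] + contrib, 0)

  values <- expected * exp(matrix(rnorm(n_rows * n, 0, d$noise_sigma),
                                  n_rows, n)) +
    abs(matrix(rnorm(n_rows * n, 0, d$noise_floor), n_rows, n))

  # isotopologues shadow their (noisy) parent column; the tiny additive
  # noise is scaled to the parent so |r| > 0.99 holds for faint parents too
  if (n_iso) {
    for (k in (n - n_iso + 1):n) {
      p <- match(parent_label[k], labels)
      tiny <- 0.02 * iso_ratio[k] * max(sd(values[, p]), 1e-6)
      values[, k] <- pmax(values[, p] * iso_ratio[k] +
                            rnorm(n_rows, 0, tiny), 0)
    }
  }
  colnames(values) <- labels
  concentrations <- as_volatilome(bind_cols(meta, as_tibble(values)),
                                  corrected = FALSE)

  ## ---- growth rates ----
  species_mean <- runif(d$n_species, 4, 10)
  strain_dev <- rnorm(n_strains, 0, 1)
  lca_species <- rnorm(d$n_species, -1.5, 0.7)
  lca_strain <- rnorm(n_strains, 0, 0.4)
  co_species <- rnorm(d$n_species, 0, 0.2)
  co_strain <- rnorm(n_strains, 0, 0.8)
  co_strain[runif(n_strains) < 1 / 3] <- 0  # some strains unaffected
  growth_sd <- 0.3
  grid <- tidyr::expand_grid(strain = strains,
                             medium = c("PDA", "LcA"),
                             mode = c("pure", "co"),
                             replicate = seq_len(d$growth_replicates))
  gi <- match(grid$strain, strains)
  si <- match(strain_species[gi], species)
  mu <- species_mean[si] + strain_dev[gi] +
    (grid$medium == "LcA") * (lca_species[si] + lca_strain[gi]) +
    (grid$mode == "co") * (co_species[si] + co_strain[gi])
  growth <- tibble(strain = grid$strain, species = strain_species[gi],
                   medium = grid$medium, mode = grid$mode,
                   replicate = grid$replicate,
                   rate = pmax(mu + rnorm(nrow(grid), 0, growth_sd), 0.1))

  truth <- structure(list(
    coefficients = tibble(strain = strains, species = strain_species,
                          a_true = a_true, b_true = b_true),
    peaks = tibble(label = labels, mz = mz, role = roles,
                   parent = parent_label, iso_ratio = iso_ratio,
                   medium_level = med_level, bacterial_level = bact_level,
                   fungal_base = fung_base, trending = trending,
                   trend_slope = trend_slope, regulated = regulated,
                   deviation_factor = dev_factor),
    fungal_signals = `dimnames<-`(fung_signal, list(strains, labels)),
    growth = list(species = tibble(species = species,
                                   mean_rate = species_mean,
                                   lca_effect = lca_species,
                                   co_effect = co_species),
                  strains = tibble(strain = strains, species = strain_species,
                                   strain_dev = strain_dev,
                                   lca_effect = lca_strain,
                                   co_effect = co_strain),
                  replicate_sd = growth_sd)),
    class = "ground_truth")

  structure(list(concentrations = concentrations, growth = growth,
                 truth = truth, design = d),
            class = "vol_experiment")
}

#' Tabular summary of a simulation's ground truth
#'
#' Returns the per-strain latent coefficients and the per-peak role table,
#' optionally writing both as CSV for use by test harnesses.
#'
#' @param truth A `ground_truth` object from [simulate_experiment()].
#' @param dir Optional output directory for `coefficients.csv` and
#'   `peaks.csv`.
#' @return A list with tibbles `coefficients` and `peaks`.
#' @export
truth_report <- function(truth, dir = NULL) {
  stopifnot(inherits(truth, "ground_truth"))
  out <- list(coefficients = truth$coefficients,
              peaks = select(truth$peaks, "label", "mz", "role", "parent",
                             "regulated", "deviation_factor", "trending"))
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    readr::write_csv(out$coefficients, file.path(dir, "coefficients.csv"),
                     progress = FALSE)
    readr::write_csv(out$peaks, file.path(dir, "peaks.csv"), progress = FALSE)
  }
  out
}
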