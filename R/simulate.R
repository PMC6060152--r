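#' Parameters for the synthetic cohort generator
#'
#' Defaults emulate the three-arm study design: arms of 7/6/6 mice, two brain
#' regions, 41 fifteen-minute bins per mouse with a 5-bin treadmill reference
#' window, 36 known analytes of which 11 drift with behavioral state
#' (z increasing while awake, decreasing while asleep) and 3 decline in all
#' states ("depletion" analytes, emulating compounds washed out by prolonged
#' sampling), whole-series and point missingness, planted outliers, unknown
#' spectral features with mass/retention-time jitter well inside the
#' clustering tolerances, and EEG band trajectories homeostatically coupled
#' to wake/sleep history.
#'
#' Slopes are expressed in baseline-noise z-units per hour in the relevant
#' state, so a `wake_slope` of 0.3 means an expected rise of 0.3 baseline
#' standard deviations per fully-awake hour. Band coupling `kappa_mag` is in
#' z-units per unit of band-power deviation; coupled analytes alternate
#' coupling sign so that both positively and negatively band-coupled
#' metabolites are planted.
#'
#' @param seed Integer seed.
#' @param n_mice_per_group Arm sizes (`S6_EW3`, `EW6_S3`, `SW6_EW3`).
#' @param n_known_analytes Number of known analytes (36).
#' @param n_state_dependent Number of wake-upregulated analytes (11).
#' @param n_depletion Number of all-state declining analytes (3).
#' @param wake_slope,sleep_slope Drift in z-units per awake / asleep hour for
#'   state-dependent analytes (0.3 / -0.3).
#' @param depletion_slope Drift per elapsed hour for depletion analytes.
#' @param noise_sd Residual sd of log-intensity per 15-min sample.
#' @param mouse_re_sd Sd of the per-(mouse, analyte) random intercept.
#' @param p_point_missing,p_hour_missing,p_series_missing Probabilities of a
#'   single missing observation, of a whole experimental hour (4 consecutive
#'   bins) undetected, and of a whole (mouse, region, analyte) series being
#'   absent. Hour-level dropouts exercise the nearest-neighbor imputation
#'   tier; series dropouts exercise the cross-mouse tier.
#' @param n_planted_outliers Number of planted single-sample outliers.
#' @param n_unknown_features Number of unknown spectral-feature clusters.
#' @param n_unknown_state_dependent How many of these drift with state (the
#'   last of them is planted sleep-upregulated, the others wake-upregulated).
#' @param mass_jitter_sd,rt_jitter_sd Within-cluster dispersion of observed
#'   mass (Da) and retention time (min); defaults are a tenth of the
#'   clustering tolerances 0.0014 Da / 0.3 min so planted clusters are
#'   recoverable.
#' @param kappa_mag Magnitude of metabolite / 2-6 Hz coupling (see above).
#' @param band_noise_sd Sd of hourly band-power fluctuations around trend.
#'
#' @return A list of class `generator_params`.
#' @export
generator_params <- function(seed = 1L,
                             n_mice_per_group = c(S6_EW3 = 7L, EW6_S3 = 6L, SW6_EW3 = 6L),
                             n_known_analytes = 36L,
                             n_state_dependent = 11L,
                             n_depletion = 3L,
                             wake_slope = 0.3,
                             sleep_slope = -0.3,
                             depletion_slope = -0.25,
                             noise_sd = 0.25,
                             mouse_re_sd = 0.3,
                             p_point_missing = 0.01,
                             p_hour_missing = 0.01,
                             p_series_missing = 0.04,
                             n_planted_outliers = 13L,
                             n_unknown_features = 8L,
                             n_unknown_state_dependent = 3L,
                             mass_jitter_sd = 0.00014,
                             rt_jitter_sd = 0.03,
                             kappa_mag = 0.008,
                             band_noise_sd = 60) {
  p <- as.list(environment())
  if (any(n_mice_per_group < 1)) stop("parameter error: each arm needs at least one mouse")
  if (n_known_analytes < 1) stop("parameter error: need at least one analyte")
  if (n_state_dependent + n_depletion > n_known_analytes) {
    stop("parameter error: state-dependent + depletion analytes exceed n_known_analytes")
  }
  if (noise_sd <= 0 || mouse_re_sd < 0) stop("parameter error: sds must be positive")
  if (any(c(p_point_missing, p_series_missing) < 0 | c(p_point_missing, p_series_missing) > 1)) {
    stop("parameter error: missingness probabilities must lie in [0,1]")
  }
  if (n_unknown_state_dependent > n_unknown_features) {
    stop("parameter error: more state-dependent unknown features than clusters")
  }
  class(p) <- "generator_params"
  p
}

# run `expr` under a private RNG stream, restoring the caller's stream after
with_local_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(expr)
}

# wake fractions are drawn hierarchically: an hour-level state tendency per
# (mouse, hour) and per-bin fractions concentrated around it. Wake/sleep
# bouts in mice are consolidated on the hour scale, so an occasional
# "wrong-state" hour contradicts the schedule in all four of its bins.
wake_fraction_pars <- function(detail) {
  switch(detail,
    wake_treadmill = NULL,                       # enforced: fully awake
    wake_novel = c(mean = 0.95, conc = 12),
    wake_spont = c(mean = 0.85, conc = 8),
    sleep = c(mean = 0.15, conc = 5),
    stop("unknown schedule state: ", detail)
  )
}

sample_wake_fractions <- function(wake) {
  mh <- paste(wake$mouse_id, wake$hour, wake$sched_detail)
  first <- !duplicated(mh)
  hour_mean <- numeric(sum(first))
  names(hour_mean) <- mh[first]
  for (i in which(first)) {
    pars <- wake_fraction_pars(wake$sched_detail[i])
    hour_mean[mh[i]] <- if (is.null(pars)) 1 else {
      stats::rbeta(1, pars["mean"] * pars["conc"], (1 - pars["mean"]) * pars["conc"])
    }
  }
  m <- hour_mean[mh]
  f <- ifelse(wake$sched_detail == "wake_treadmill", 1,
              stats::rbeta(length(m), pmax(m, 1e-3) * 40, pmax(1 - m, 1e-3) * 40))
  unname(f)
}

simulate_analyte_roles <- function(params) {
  n <- params$n_known_analytes
  role <- rep("null", n)
  role[seq_len(params$n_state_dependent)] <- "state"
  if (params$n_depletion > 0) {
    role[params$n_state_dependent + seq_len(params$n_depletion)] <- "depletion"
  }
  kappa <- rep(0, n)
  idx_state <- which(role == "state")
  if (length(idx_state) > 0) {
    kappa[idx_state] <- params$kappa_mag * (-1)^(seq_along(idx_state) - 1)
  }
  tibble::tibble(
    analyte_id = sprintf("known_%02d", seq_len(n)),
    role = role,
    wake_slope = ifelse(role == "state", params$wake_slope, 0),
    sleep_slope = ifelse(role == "state", params$sleep_slope, 0),
    depletion_slope = ifelse(role == "depletion", params$depletion_slope, 0),
    kappa = kappa,
    base_log = stats::runif(n, log(1e5), log(1e7))
  )
}

#' Simulate a full study-shaped cohort with known ground truth
#'
#' Generates, under one seed: per-bin wake fractions following each arm's
#' schedule; raw ion intensities as
#' `exp(base + mouse intercept + state-integral drift + band coupling + noise)`
#' so that values are positive and baseline z-scoring is nontrivial; hourly
#' EEG band powers (2-6 Hz rising with cumulative wake, slow-wave activity
#' decaying across recovery sleep, gamma flat and uncoupled); unknown
#' spectral features emitted as jittered (mass, retention time) observations
#' around well-separated cluster centers; and planted artifacts
#' (whole-series missingness, point missingness, single-sample outliers) via
#' [plant_artifacts()].
#'
#' Metabolite drift is modeled as an integral of state occupancy: each
#' fully-awake hour moves a wake-upregulated analyte's expected z by
#' `wake_slope` and each asleep hour by `sleep_slope`, producing the roughly
#' linear hour-scale trends characteristic of state-coupled dialysate
#' metabolites. Depletion analytes decline in every state and must be
#' excluded by the downstream state-specificity rule.
#'
#' @param params A [generator_params()] object.
#' @return A list with elements `samples` (long intensity table), `wake`
#'   (wake-fraction table), `bands` (band-power table), `features` (unknown
#'   spectral-feature table) and `truth` (ground-truth list: analyte roles and
#'   slopes, per-mouse intercepts, planted artifact coordinates, feature
#'   cluster assignments, band coupling coefficients and the analytically
#'   expected sign of each coupled analyte's pooled correlation with 2-6 Hz
#'   power).
#' @export
simulate_cohort <- function(params = generator_params()) {
  stopifnot(inherits(params, "generator_params"))
  with_local_seed(params$seed, {
    design <- study_design(params$n_mice_per_group)
    mice <- design_mice(design)
    sched <- scheduled_states(design)

    # --- wake fractions ---------------------------------------------------
    wake <- dplyr::inner_join(mice, sched, by = "group", relationship = "many-to-many")
    wake <- dplyr::arrange(wake, .data$mouse_id, .data$bin_index)
    wake$wake_fraction <- sample_wake_fractions(wake)
    # cumulative awake / asleep hours within the experimental window
    wake <- dplyr::group_by(wake, .data$mouse_id)
    wake <- dplyr::mutate(wake,
      exp_bin = is.na(.data$hour) == FALSE,
      awake_h = cumsum(ifelse(.data$exp_bin, .data$wake_fraction, 0)) / 4,
      asleep_h = cumsum(ifelse(.data$exp_bin, 1 - .data$wake_fraction, 0)) / 4,
      elapsed_h = cumsum(as.numeric(.data$exp_bin)) / 4
    )
    wake <- dplyr::ungroup(wake)

    # --- EEG band powers --------------------------------------------------
    hour_state <- dplyr::filter(wake, .data$exp_bin)
    hour_state <- dplyr::group_by(hour_state, .data$mouse_id, .data$group, .data$hour)
    hour_state <- dplyr::summarise(hour_state,
      awake_h = max(.data$awake_h), asleep_h = max(.data$asleep_h),
      wake_frac = mean(.data$wake_fraction), .groups = "drop"
    )
    n_mh <- nrow(hour_state)
    low_dev <- stats::rnorm(n_mh, 0, params$band_noise_sd)
    bands <- dplyr::mutate(hour_state,
      low_2_6 = pmax(100 + 8 * .data$awake_h + low_dev, 1),
      swa_0p5_4 = pmax(ifelse(.data$wake_frac < 0.5,
                              220 - 35 * .data$asleep_h,
                              60) + stats::rnorm(n_mh, 0, params$band_noise_sd), 1),
      gamma_40_100 = pmax(50 + stats::rnorm(n_mh, 0, params$band_noise_sd / 2), 1),
      low_dev = low_dev
    )
    band_tbl <- tidyr::pivot_longer(
      bands[c("mouse_id", "hour", "low_2_6", "swa_0p5_4", "gamma_40_100")],
      cols = dplyr::all_of(eeg_bands), names_to = "band", values_to = "power"
    )
    band_tbl <- dplyr::arrange(band_tbl, .data$mouse_id, .data$hour, .data$band)

    # --- known analyte intensities ---------------------------------------
    analytes <- simulate_analyte_roles(params)
    intercepts <- tidyr::expand_grid(mouse_id = mice$mouse_id,
                                     analyte_id = analytes$analyte_id)
    intercepts$intercept <- stats::rnorm(nrow(intercepts), 0, params$mouse_re_sd)

    grid <- tidyr::expand_grid(
      wake[c("mouse_id", "group", "bin_index", "hour",
             "awake_h", "asleep_h", "elapsed_h")],
      region = design$regions
    )
    grid <- dplyr::left_join(grid, bands[c("mouse_id", "hour", "low_dev")],
                             by = c("mouse_id", "hour"))
    grid$low_dev[is.na(grid$low_dev)] <- 0
    grid <- tidyr::expand_grid(grid, analyte_id = analytes$analyte_id)
    grid <- dplyr::left_join(grid, analytes, by = "analyte_id")
    grid <- dplyr::left_join(grid, intercepts, by = c("mouse_id", "analyte_id"))
    log_x <- grid$base_log + grid$intercept +
      params$noise_sd * (grid$wake_slope * grid$awake_h +
                         grid$sleep_slope * grid$asleep_h +
                         grid$depletion_slope * grid$elapsed_h +
                         grid$kappa * grid$low_dev) +
      stats::rnorm(nrow(grid), 0, params$noise_sd)
    samples <- tibble::tibble(
      mouse_id = grid$mouse_id, group = grid$group, region = grid$region,
      analyte_id = grid$analyte_id, bin_index = grid$bin_index,
      intensity = exp(log_x)
    )
    samples <- dplyr::arrange(samples, .data$mouse_id, .data$region,
                              .data$analyte_id, .data$bin_index)

    # --- unknown spectral features ---------------------------------------
    feats <- simulate_features(params, design, mice, wake, bands)

    # --- artifacts --------------------------------------------------------
    planted <- plant_artifacts(samples, params, design)

    # analytically expected sign of the pooled (EW6 hours 1-6) correlation of
    # each coupled analyte with 2-6 Hz power: trend covariance + coupling
    h <- 1:6
    var_h_pop <- mean((h - mean(h))^2)
    analytes$expected_sign_low26 <- ifelse(
      analytes$kappa == 0, NA_real_,
      sign(analytes$wake_slope * 8 * var_h_pop +
           analytes$kappa * params$band_noise_sd^2)
    )

    truth <- list(
      design = design,
      analytes = analytes,
      mouse_intercepts = intercepts,
      outliers = planted$outliers,
      missing_series = planted$missing_series,
      missing_points = planted$missing_points,
      missing_hours = planted$missing_hours,
      feature_clusters = feats$clusters,
      band_trend = list(low_2_6_slope_per_wake_hour = 8,
                        swa_decay_per_sleep_hour = -35)
    )
    list(samples = planted$table,
         wake = wake[c("mouse_id", "bin_index", "wake_fraction")],
         bands = band_tbl[c("mouse_id", "hour", "band", "power")],
         features = feats$features,
         truth = truth)
  })
}

simulate_features <- function(params, design, mice, wake, bands) {
  k <- params$n_unknown_features
  if (k == 0) {
    return(list(features = tibble::tibble(
      mass = numeric(), rt = numeric(), mouse_id = character(),
      group = character(), region = character(), bin_index = integer(),
      intensity = numeric()), clusters = tibble::tibble()))
  }
  # well-separated cluster centers: at least 10x the clustering tolerances
  mass0 <- sort(stats::runif(k, 80, 500))
  while (k > 1 && min(diff(mass0)) < 0.014) mass0 <- sort(stats::runif(k, 80, 500))
  rt0 <- stats::runif(k, 1, 13)
  nsd <- params$n_unknown_state_dependent
  role <- rep("null", k)
  if (nsd > 0) {
    role[seq_len(nsd)] <- "state"
  }
  dir <- rep(0, k)
  if (nsd > 0) dir[seq_len(nsd)] <- c(rep(1, nsd - 1), -1)  # last one sleep-up
  clusters <- tibble::tibble(
    cluster = sprintf("unk_%02d", seq_len(k)),
    mass = mass0, rt = rt0, role = role, direction = dir,
    base_log = stats::runif(k, log(1e5), log(1e6))
  )
  grid <- tidyr::expand_grid(
    wake[c("mouse_id", "group", "bin_index", "awake_h", "asleep_h")],
    region = design$regions,
    cluster = clusters$cluster
  )
  grid <- dplyr::left_join(grid, clusters, by = "cluster")
  log_x <- grid$base_log +
    params$noise_sd * grid$direction *
      (params$wake_slope * grid$awake_h + params$sleep_slope * grid$asleep_h) +
    stats::rnorm(nrow(grid), 0, params$noise_sd)
  detected <- stats::runif(nrow(grid)) < 0.95
  features <- tibble::tibble(
    mass = grid$mass + stats::rnorm(nrow(grid), 0, params$mass_jitter_sd),
    rt = pmax(grid$rt + stats::rnorm(nrow(grid), 0, params$rt_jitter_sd), 0),
    mouse_id = grid$mouse_id, group = grid$group, region = grid$region,
    bin_index = grid$bin_index, intensity = exp(log_x),
    true_cluster = grid$cluster
  )[detected, ]
  list(features = features, clusters = clusters)
}

#' Plant missingness and outlier artifacts into a clean intensity table
#'
#' Blanks whole (mouse, region, analyte) series with probability
#' `p_series_missing`, blanks remaining single observations with probability
#' `p_point_missing`, and replaces `n_planted_outliers` observed
#' post-reference samples (at most one per series) with a value whose
#' baseline z-score is 7 times the largest absolute z-score of the rest of
#' its series, guaranteeing that the downstream 5x outlier rule fires on
#' exactly the planted coordinates.
#'
#' @param table A clean long intensity table.
#' @param params A [generator_params()].
#' @param design The [study_design()]; defaults to the one implied by
#'   `params`.
#' @return A list with `table` (artifacts applied), `missing_series`,
#'   `missing_points` and `outliers` coordinate tibbles.
#' @export
plant_artifacts <- function(table, params, design = study_design(params$n_mice_per_group)) {
  key <- c("mouse_id", "region", "analyte_id")
  series <- unique(table[key])
  n_series <- nrow(series)
  blank_series <- series[stats::runif(n_series) < params$p_series_missing, ]
  tab <- dplyr::left_join(table,
                          dplyr::mutate(blank_series, .blank = TRUE), by = key)
  tab$intensity[!is.na(tab$.blank)] <- NA_real_
  tab$.blank <- NULL

  pt <- !is.na(tab$intensity) & stats::runif(nrow(tab)) < params$p_point_missing
  missing_points <- tab[pt, c(key, "bin_index")]
  tab$intensity[pt] <- NA_real_

  # whole-hour dropouts among experimental hours
  hr <- hour_of_bin(design, tab$bin_index)
  sh <- paste(tab$mouse_id, tab$region, tab$analyte_id, hr)
  exp_cells <- unique(sh[!is.na(hr)])
  blank_hours <- exp_cells[stats::runif(length(exp_cells)) < params$p_hour_missing]
  hh <- !is.na(hr) & sh %in% blank_hours
  missing_hours <- dplyr::distinct(
    dplyr::mutate(tab[hh, key], hour = hr[hh])
  )
  tab$intensity[hh] <- NA_real_

  # plant outliers in observed post-reference samples, one series at most once
  n_out <- params$n_planted_outliers
  outliers <- tab[0, c(key, "bin_index")]
  if (n_out > 0) {
    ref <- reference_bins(design)
    cand <- which(!is.na(tab$intensity) & !(tab$bin_index %in% ref))
    cand <- cand[sample.int(length(cand))]
    cand_key <- paste(tab$mouse_id[cand], tab$region[cand], tab$analyte_id[cand])
    cand <- cand[!duplicated(cand_key)]
    picked <- integer(0)
    for (i in cand) {
      if (length(picked) >= n_out) break
      s <- tab$mouse_id == tab$mouse_id[i] & tab$region == tab$region[i] &
        tab$analyte_id == tab$analyte_id[i]
      refv <- tab$intensity[s & tab$bin_index %in% ref]
      refv <- refv[!is.na(refv)]
      if (length(refv) < 2 || stats::sd(refv) == 0) next
      mu <- mean(refv); sg <- stats::sd(refv)
      z <- abs((tab$intensity[s] - mu) / sg)
      z[match(tab$bin_index[i], tab$bin_index[s])] <- NA
      m <- max(z, na.rm = TRUE)
      if (!is.finite(m) || m == 0) next
      tab$intensity[i] <- mu + 7 * m * sg
      picked <- c(picked, i)
    }
    if (length(picked) < n_out) {
      stop("parameter error: requested outliers exceed plantable cells")
    }
    outliers <- tab[picked, c(key, "bin_index")]
  }
  list(table = tab, missing_series = blank_series,
       missing_points = missing_points, missing_hours = missing_hours,
       outliers = outliers)
}
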