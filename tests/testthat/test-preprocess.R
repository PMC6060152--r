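make_zm <- function(df) {
  # minimal z-matrix constructor for imputation tests
  df$provenance <- ifelse(is.na(df$z), "missing", "observed")
  df$n_obs <- ifelse(is.na(df$z), 0L, 4L)
  tibble::as_tibble(df)
}

test_that("detection filter requires min_mice observed in every arm, per region", {
  d <- study_design()
  mice <- design_mice(d)
  grid <- tidyr::expand_grid(mice[c("mouse_id", "group")], region = d$regions,
                             analyte_id = c("a1", "a2"), bin_index = 0:40)
  grid$intensity <- 100
  # a2 observed in only 2 mice of EW6_S3 in M1: excluded there, kept in mPFC
  ew_mice <- mice$mouse_id[mice$group == "EW6_S3"]
  drop <- grid$analyte_id == "a2" & grid$region == "M1" &
    grid$mouse_id %in% ew_mice[-(1:2)]
  grid$intensity[drop] <- NA_real_
  kept <- detection_filter(grid, d, min_mice = 3)
  expect_true(all(c("a1", "a2") %in% kept$analyte_id[kept$region == "mPFC"]))
  expect_false("a2" %in% kept$analyte_id[kept$region == "M1"])
  expect_error(detection_filter(grid, d, min_mice = 10), "parameter error")
})

test_that("detection filter equals a brute-force recount on synthetic data", {
  d <- study_design()
  sim <- small_cohort(seed = 6)
  kept <- detection_filter(sim$samples, d, min_mice = 3)
  brute <- list()
  for (r in d$regions) for (a in unique(sim$samples$analyte_id)) {
    ok <- TRUE
    for (g in d$groups$group) {
      sub <- sim$samples[sim$samples$region == r & sim$samples$analyte_id == a &
                           sim$samples$group == g & !is.na(sim$samples$intensity), ]
      if (length(unique(sub$mouse_id)) < 3) ok <- FALSE
    }
    if (ok) brute[[length(brute) + 1]] <- c(r, a)
  }
  brute <- do.call(rbind, brute)
  expect_setequal(paste(kept$region, kept$analyte_id),
                  paste(brute[, 1], brute[, 2]))
})

test_that("baseline z-scores match an independent two-pass computation", {
  d <- study_design()
  set.seed(31)
  tab <- toy_long_table(n_analytes = 2, regions = "mPFC", design = d)
  tab$intensity <- stats::rlnorm(nrow(tab), 10, 0.4)
  zs <- baseline_zscore(tab, d)
  one <- zs$z[zs$z$mouse_id == "m1" & zs$z$analyte_id == "a01", ]
  raw <- tab[tab$mouse_id == "m1" & tab$analyte_id == "a01", ]
  ref <- raw$intensity[raw$bin_index %in% 0:4]
  mu <- sum(ref) / length(ref)
  sg <- sqrt(sum((ref - mu)^2) / (length(ref) - 1))
  expect_equal(one$z, (raw$intensity - mu) / sg, tolerance = 1e-12)
})

test_that("z-scoring drops degenerate series and is affine invariant", {
  d <- study_design()
  tab <- toy_long_table(n_analytes = 1, regions = "mPFC", design = d)
  # constant reference window: sd 0 -> dropped with reason
  tab$intensity[tab$mouse_id == "m1" & tab$bin_index %in% 0:4] <- 7
  zs <- baseline_zscore(tab, d)
  expect_equal(nrow(zs$dropped), 1)
  expect_match(zs$dropped$reason, "zero reference")
  expect_false("m1" %in% zs$z$mouse_id)

  set.seed(8)
  tab2 <- toy_long_table(n_analytes = 1, regions = "mPFC", design = d)
  tab2$intensity <- stats::rlnorm(nrow(tab2), 8, 0.5)
  z0 <- baseline_zscore(tab2, d)$z$z
  shifted <- tab2; shifted$intensity <- 3 * shifted$intensity + 120
  z1 <- baseline_zscore(shifted, d)$z$z
  expect_equal(z0, z1, tolerance = 1e-10)
})

test_that("the 5x outlier rule flags exactly the dominating observation", {
  expect_equal(flag_outlier_series(c(1, 1, 1, 10)), 4L)
  expect_equal(flag_outlier_series(c(1, 1, 1, 4)), integer(0))
  expect_equal(flag_outlier_series(c(2, 2, 2, 2)), integer(0))
  expect_equal(flag_outlier_series(c(-8, 1, 1, 1)), 1L)   # symmetric in |z|
  expect_equal(flag_outlier_series(c(1, NA, 1, 10, NA)), 4L)
  expect_warning(out <- flag_outlier_series(c(NA, 3, NA)), "single observation")
  expect_equal(out, integer(0))
})

test_that("wrong-state filtering is strict and symmetric", {
  d <- study_design()
  # S6_EW3 scheduled asleep in hours 1-6; SW6_EW3 scheduled awake
  tab <- tibble::tibble(
    mouse_id = c("m1", "m1", "m2"), group = c("S6_EW3", "S6_EW3", "SW6_EW3"),
    region = "mPFC", analyte_id = "a", bin_index = c(8L, 12L, 8L), z = 1
  )
  wake <- tibble::tibble(mouse_id = c("m1", "m1", "m2"),
                         bin_index = c(8L, 12L, 8L),
                         wake_fraction = c(0.6, 0.5, 0.2))
  out <- wrong_state_filter(tab, wake, d)
  # 0.6 awake while scheduled asleep -> discarded; exactly 0.5 retained;
  # 0.8 asleep while scheduled awake -> discarded
  expect_equal(nrow(out$table), 1)
  expect_equal(out$table$bin_index, 12L)
  expect_equal(nrow(out$discarded), 2)
  expect_error(wrong_state_filter(tab, wake[-1, ], d), "integrity")
})

test_that("coarse-graining averages 4-bin blocks and keeps partial blocks", {
  d <- study_design()
  zt <- tibble::tibble(
    mouse_id = "m1", group = "S6_EW3", region = "mPFC", analyte_id = "a",
    bin_index = 0:40,
    z = c(rep(0, 5), 1, 2, 3, 4, 1, NA, 3, NA, rep(NA, 4), rep(0.5, 24))
  )
  zm <- coarse_grain(zt, d)
  expect_equal(nrow(zm), 9)
  expect_equal(zm$z[zm$hour == 1], 2.5)
  expect_equal(zm$z[zm$hour == 2], 2.0)
  expect_true(is.na(zm$z[zm$hour == 3]))
  expect_equal(zm$provenance[zm$hour == 3], "missing")
  expect_equal(zm$n_obs[zm$hour == 2], 2L)
})

test_that("tier-2 imputation averages the two nearest observed hours", {
  zm <- make_zm(tibble::tibble(
    mouse_id = "m1", group = "S6_EW3", region = "mPFC", analyte_id = "a",
    hour = 1:9, z = c(0, 0, 0, 1, NA, 3, 0, 0, 0)
  ))
  out <- impute_zmatrix(zm)
  expect_equal(out$z[out$hour == 5], 2.0)
  expect_equal(out$provenance[out$hour == 5], "imputed_tier2")

  # edge gap: both neighbors on one side
  zm2 <- make_zm(tibble::tibble(
    mouse_id = "m1", group = "S6_EW3", region = "mPFC", analyte_id = "a",
    hour = 1:9, z = c(NA, NA, 6, 2, 4, 4, 4, 4, 4)
  ))
  out2 <- impute_zmatrix(zm2)
  expect_equal(out2$z[out2$hour == 1], 4)   # hours 3 and 4 -> (6+2)/2
  expect_equal(out2$z[out2$hour == 2], 4)

  # a single observed hour is copied
  zm3 <- make_zm(tibble::tibble(
    mouse_id = "m1", group = "S6_EW3", region = "mPFC", analyte_id = "a",
    hour = 1:9, z = c(rep(NA, 4), 1.5, rep(NA, 4))
  ))
  expect_true(all(impute_zmatrix(zm3)$z == 1.5))
})

test_that("tier-1 imputation uses the cross-mouse condition mean", {
  base <- tidyr::expand_grid(
    mouse_id = sprintf("m%d", 1:6), hour = 1:9
  )
  base$group <- "S6_EW3"; base$region <- "mPFC"; base$analyte_id <- "a"
  base$z <- 0.1 * match(base$mouse_id, sprintf("m%d", 1:6)) - 0.1
  base$z[base$mouse_id == "m6"] <- NA          # whole series missing
  zm <- make_zm(base)
  out <- impute_zmatrix(zm)
  filled <- out$z[out$mouse_id == "m6"]
  expect_equal(filled, rep(mean(c(0, 0.1, 0.2, 0.3, 0.4)), 9))
  expect_true(all(out$provenance[out$mouse_id == "m6"] == "imputed_tier1"))

  # no donor anywhere -> integrity error naming the coordinates
  solo <- make_zm(tibble::tibble(
    mouse_id = "m1", group = "S6_EW3", region = "mPFC", analyte_id = "a",
    hour = 1:9, z = NA_real_
  ))
  expect_error(impute_zmatrix(solo), "neither tier")
})

test_that("imputation is idempotent and the audit fraction matches a recount", {
  d <- study_design()
  sim <- small_cohort(seed = 13)
  pp <- preprocess_cohort(sim$samples, sim$wake, d)
  expect_false(any(is.na(pp$zmatrix$z)))
  again <- impute_zmatrix(pp$zmatrix)
  expect_equal(again$z, pp$zmatrix$z)
  recount <- sum(pp$zmatrix$provenance != "observed") / nrow(pp$zmatrix)
  expect_equal(pp$audit$imputed_fraction, recount)
  expect_equal(pp$audit$n_imputed_tier1 + pp$audit$n_imputed_tier2,
               sum(pp$zmatrix$provenance != "observed"))
  expect_gt(pp$audit$n_imputed_tier1, 0)
  expect_gt(pp$audit$n_imputed_tier2, 0)
})

test_that("heatmap matrices are antisymmetric and track planted drift", {
  d <- study_design()
  sim <- small_cohort(seed = 19)
  pp <- preprocess_cohort(sim$samples, sim$wake, d)
  m_ab <- heatmap_matrix(pp$zmatrix, "EW6_S3", "S6_EW3", "mPFC")
  m_ba <- heatmap_matrix(pp$zmatrix, "S6_EW3", "EW6_S3", "mPFC")
  expect_equal(m_ab, -m_ba)
  m_aa <- heatmap_matrix(pp$zmatrix, "EW6_S3", "EW6_S3", "mPFC")
  expect_true(all(abs(m_aa) < 1e-12))
  # wake-upregulated analytes: wake-minus-sleep difference grows with hours
  tr <- sim$truth$analytes
  state_rows <- rownames(m_ab) %in% tr$analyte_id[tr$role == "state"]
  deltas <- m_ab[state_rows, , drop = FALSE]
  expect_gt(mean(deltas[, 6] - deltas[, 1]), 0)
  expect_true(all(deltas[, 6] > deltas[, 1]))
})
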