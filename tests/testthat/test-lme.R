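# small repeated-measures dataset with a genuine condition-by-time effect
toy_lme_data <- function(seed = 1, n_mice = 10, slope_gap = 0.5,
                         mouse_sd = 0.5, noise_sd = 0.4) {
  set.seed(seed)
  d <- tidyr::expand_grid(mouse = seq_len(n_mice), hour = 1:6)
  d$cond <- factor(ifelse(d$mouse <= n_mice / 2, "A", "B"))
  b <- stats::rnorm(n_mice, 0, mouse_sd)
  d$y <- b[d$mouse] + ifelse(d$cond == "B", slope_gap, 0) * d$hour +
    stats::rnorm(nrow(d), 0, noise_sd)
  tibble::tibble(y = d$y, mouse_id = factor(d$mouse), cond = d$cond,
                 hour = d$hour, region = factor("mPFC"))
}

test_that("maximum-likelihood fits agree with an independent mixed-model implementation", {
  skip_if_not_installed("nlme")
  data <- toy_lme_data(seed = 5)
  ours <- sleepmetab:::fit_ml(data, c("cond", "hour", "cond:hour"),
                              "(1 | mouse_id)")
  ref <- nlme::lme(y ~ cond * hour, random = ~ 1 | mouse_id, data = data,
                   method = "ML")
  expect_equal(as.numeric(logLik(ours)), as.numeric(logLik(ref)),
               tolerance = 1e-4)
  fe_ours <- lme4::fixef(ours)
  fe_ref <- nlme::fixef(ref)
  expect_equal(unname(fe_ours[c("(Intercept)", "condB", "hour")]),
               unname(fe_ref[c("(Intercept)", "condB", "hour")]),
               tolerance = 1e-4)
  # AIC identity on the same fit
  k <- attr(logLik(ours), "df")
  expect_equal(AIC(ours), 2 * k - 2 * as.numeric(logLik(ours)),
               tolerance = 1e-8)
})

test_that("transform selection prefers identity for symmetric data, log for lognormal", {
  set.seed(2)
  gauss <- tibble::tibble(y = stats::rnorm(300), hour = rep(1:6, 50))
  expect_equal(choose_transform(gauss, "hour")$name, "identity")
  hits <- 0
  for (s in 1:10) {
    set.seed(s)
    ln <- tibble::tibble(y = stats::rlnorm(300, 0, 1), hour = rep(1:6, 50))
    if (choose_transform(ln, "hour")$name == "log") hits <- hits + 1
  }
  expect_gte(hits, 9)
  const <- tibble::tibble(y = rep(2, 20), hour = rep(1:5, 4))
  expect_equal(choose_transform(const, "hour")$name, "identity")
})

test_that("random-slope support is detected from the data", {
  keep <- 0; drop <- 0
  for (s in 1:6) {
    set.seed(s)
    n_mice <- 12
    d <- tidyr::expand_grid(mouse = seq_len(n_mice), hour = 1:9)
    slopes <- stats::rnorm(n_mice, 0, 0.5)
    inter <- stats::rnorm(n_mice, 0, 0.5)
    d$y <- inter[d$mouse] + slopes[d$mouse] * d$hour +
      stats::rnorm(nrow(d), 0, 0.3)
    data <- tibble::tibble(y = d$y, mouse_id = factor(d$mouse),
                           cond = factor(rep(c("A", "B"), length.out = nrow(d))),
                           hour = d$hour, region = factor("mPFC"))
    if (select_random_effects(data, "hour") == "(1 + hour | mouse_id)") {
      keep <- keep + 1
    }
    d$y <- stats::rnorm(nrow(d), 0, 0.3)       # no mouse-specific slope
    data$y <- d$y
    if (select_random_effects(data, "hour") == "(1 | mouse_id)") drop <- drop + 1
  }
  expect_gte(keep, 4)
  expect_gte(drop, 4)
  one_mouse <- tibble::tibble(y = stats::rnorm(9), mouse_id = factor("m1"),
                              cond = factor(rep(c("A", "B"), length.out = 9)),
                              hour = 1:9, region = factor("mPFC"))
  expect_null(select_random_effects(one_mouse, "hour"))
})

test_that("AIC structure selection tracks the data, carrying the condition block", {
  hits <- 0
  for (s in 1:6) {
    data <- toy_lme_data(seed = s, slope_gap = 0.5)
    sel <- select_fixed_effects(data, "(1 | mouse_id)")
    # a planted slope difference implies a time trend, so the tested model
    # must carry the condition-by-time interaction
    if (all(c("hour", "cond", "cond:hour") %in% sel$terms)) hits <- hits + 1
  }
  expect_gte(hits, 5)
  # pure noise: no time trend selected, condition block reduces to the main
  # effect (condition itself is never dropped - it is the tested term)
  sparse <- 0
  for (s in 1:6) {
    data <- toy_lme_data(seed = 100 + s, slope_gap = 0)
    data$y <- stats::rnorm(nrow(data))
    sel <- select_fixed_effects(data, "(1 | mouse_id)")
    if (!("hour" %in% sel$structure)) sparse <- sparse + 1
    expect_true("cond" %in% sel$terms)
  }
  expect_gte(sparse, 4)
})

test_that("the condition LRT is nonnegative, typed, and detects planted effects", {
  data <- toy_lme_data(seed = 7, slope_gap = 0.6)
  sel <- select_fixed_effects(data, "(1 | mouse_id)")
  tst <- test_condition(data, sel$terms, "(1 | mouse_id)")
  expect_gte(tst$stat, 0)
  expect_lt(tst$p, 0.01)
  expect_equal(tst$effect_type, "interaction")
  # removing the effect entirely: p near 1 is not required, but the statistic
  # must stay nonnegative on null data too
  null_data <- toy_lme_data(seed = 8, slope_gap = 0)
  null_data$y <- stats::rnorm(nrow(null_data))
  tst0 <- test_condition(null_data, character(0), "(1 | mouse_id)")
  expect_gte(tst0$stat, 0)
  expect_true(tst0$p > 0 && tst0$p <= 1)
})

test_that("state-specificity verdicts follow the two-criteria rule", {
  w <- "wake_higher"; s <- "sleep_higher"
  # significant in >=1 model with concordant directions
  expect_true(state_specificity(c(0.0032, 0.0007, 0.1291), c(w, w, w)))
  # significant but discordant directions
  expect_false(state_specificity(c(0.01, 0.2, 0.3), c(w, s, w)))
  # concordant but nowhere significant
  expect_false(state_specificity(c(0.08, 0.9, 0.12), c(w, w, w)))
  # a skipped model leaves the verdict undetermined
  expect_true(is.na(state_specificity(c(0.01, NA, 0.3), c(w, w, w))))
  expect_true(is.na(state_specificity(c(0.01, 0.2, 0.3), c(w, NA, w))))
})

test_that("full pipeline verdicts recover planted state-dependence on a small cohort", {
  d <- study_design()
  sim <- small_cohort(seed = 23)
  pp <- preprocess_cohort(sim$samples, sim$wake, d)
  tr <- sim$truth$analytes
  ids <- c(tr$analyte_id[tr$role == "state"][1:2],
           tr$analyte_id[tr$role == "depletion"][1],
           tr$analyte_id[tr$role == "null"][1])
  v <- analyte_state_tests(pp$zmatrix, d, analytes = ids)
  v$role <- tr$role[match(v$analyte_id, tr$analyte_id)]
  expect_true(all(v$state_specific[v$role == "state"]))
  expect_true(all(v$dir_between[v$role == "state"] == "wake_higher"))
  # depletion declines everywhere: must not be called state-specific
  expect_false(any(v$state_specific[v$role == "depletion"]))
})

test_that("sleep-phase typing separates planted decline dynamics", {
  build_phase_cohort <- function(seed, early_slope, recovery_slope) {
    set.seed(seed)
    d <- study_design()
    mice <- design_mice(d)
    zm <- tidyr::expand_grid(mice[c("mouse_id", "group")], region = "mPFC",
                             analyte_id = "a", hour = 1:9)
    b <- stats::rnorm(nrow(mice), 0, 0.2)
    names(b) <- mice$mouse_id
    zm$z <- stats::rnorm(nrow(zm), 0, 0.25) + b[zm$mouse_id]
    es <- zm$group == "S6_EW3" & zm$hour <= 3
    ls <- zm$group == "S6_EW3" & zm$hour >= 4 & zm$hour <= 6
    rs <- zm$group == "EW6_S3" & zm$hour >= 7
    zm$z[es] <- zm$z[es] + early_slope * zm$hour[es]
    zm$z[ls] <- zm$z[ls] - 0.05 * (zm$hour[ls] - 3)
    zm$z[rs] <- zm$z[rs] + recovery_slope * (zm$hour[rs] - 6)
    zm
  }
  d <- study_design()
  # recovery much steeper than early: Type 2
  zm <- build_phase_cohort(1, early_slope = -0.3, recovery_slope = -1.0)
  res <- sleep_phase_model(zm, d, "mPFC")
  expect_lt(res$p_interaction, 0.05)
  expect_lt(res$slopes["recovery"], res$slopes["early"])
  expect_equal(classify_sleep_pattern(res$slopes, res$contrast_p,
                                      res$p_interaction), "Type2")
  # early much steeper than recovery: Type 3
  zm <- build_phase_cohort(2, early_slope = -1.0, recovery_slope = -0.3)
  res <- sleep_phase_model(zm, d, "mPFC")
  expect_equal(classify_sleep_pattern(res$slopes, res$contrast_p,
                                      res$p_interaction), "Type3")
  # rising early phase with a significant interaction: "other"
  zm <- build_phase_cohort(3, early_slope = 0.8, recovery_slope = -0.8)
  res <- sleep_phase_model(zm, d, "mPFC")
  expect_equal(classify_sleep_pattern(res$slopes, res$contrast_p,
                                      res$p_interaction), "other")
  # matched dynamics: no type assigned when the interaction is null
  zm <- build_phase_cohort(4, early_slope = -0.05, recovery_slope = -0.05)
  zm$z[zm$group == "S6_EW3" & zm$hour >= 4 & zm$hour <= 6] <-
    zm$z[zm$group == "S6_EW3" & zm$hour >= 4 & zm$hour <= 6]
  res <- sleep_phase_model(zm, d, "mPFC")
  if (res$p_interaction >= 0.05) {
    expect_true(is.na(classify_sleep_pattern(res$slopes, res$contrast_p,
                                             res$p_interaction)))
  }
  # direct unit case: equal negative slopes, non-significant contrast
  expect_equal(classify_sleep_pattern(c(early = -0.3, recovery = -0.35),
                                      contrast_p = 0.6, p_interaction = 0.01),
               "Type1")
})
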