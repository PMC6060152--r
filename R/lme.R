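#' @importFrom stats AIC logLik pchisq pnorm vcov model.matrix reformulate
NULL

sample_skewness <- function(x) {
  x <- x[is.finite(x)]
  if (length(x) < 3) return(NA_real_)
  m <- mean(x)
  s2 <- mean((x - m)^2)
  if (s2 == 0) return(NA_real_)
  mean((x - m)^3) / s2^1.5
}

#' Choose a variance-stabilizing response transform
#'
#' Considers identity, log and square-root transforms of the response. Since
#' z-scores can be negative, log and sqrt operate on min-shifted values
#' `y - min(y) + 1`; the shift is recorded. The transform minimizing the
#' absolute skewness of the residuals of a pilot (fixed-effects-only) fit is
#' selected; identity wins ties and degenerate cases.
#'
#' @param data Model data with response column `y`.
#' @param fixed_terms Character vector of fixed-effect terms for the pilot
#'   fit (empty = intercept only).
#' @return List with `name` (`"identity"`, `"log"`, `"sqrt"`), `shift`, and
#'   `apply` (function transforming a numeric vector).
#' @export
choose_transform <- function(data, fixed_terms = character(0)) {
  shift <- 1 - min(data$y)
  cands <- list(
    identity = function(y) y,
    log = function(y) log(y + shift),
    sqrt = function(y) sqrt(y + shift)
  )
  rhs <- if (length(fixed_terms) == 0) "1" else paste(fixed_terms, collapse = " + ")
  skews <- vapply(cands, function(f) {
    yt <- f(data$y)
    if (!all(is.finite(yt))) return(NA_real_)
    fit <- try(stats::lm(stats::as.formula(paste("yt ~", rhs)),
                         data = cbind(data, yt = yt)), silent = TRUE)
    if (inherits(fit, "try-error")) return(NA_real_)
    abs(sample_skewness(stats::residuals(fit)))
  }, numeric(1))
  if (all(is.na(skews))) {
    pick <- "identity"
  } else {
    pick <- names(skews)[which.min(skews)]   # which.min drops NAs; ties -> first (identity)
  }
  list(name = pick, shift = if (pick == "identity") 0 else shift, apply = cands[[pick]])
}

# candidate non-condition structures: hierarchy-respecting subsets of
# {hour, region}; region terms only offered when the data has >1 region.
# With force_hour the time trend is kept in every candidate: in the
# within-group models the behavioral phase is itself a function of time
# (late hours), so dropping the trend aliases slow drift into the phase
# contrast and distorts its test.
structure_candidate_sets <- function(has_region, force_hour = FALSE) {
  sets <- list(character(0), "hour")
  if (has_region) sets <- c(sets, list("region", c("hour", "region")))
  if (force_hour) {
    sets <- unique(lapply(sets, function(s) union(s, "hour")))
  }
  sets
}

# deterministic condition block given a non-condition structure: the
# condition main effect plus its interaction with every structural term
# present. Letting model selection pick among condition terms and then
# likelihood-ratio testing the term it picked is anticonservative
# (post-selection inference), so condition terms are never AIC-selected.
with_condition_block <- function(structure_terms) {
  out <- c(structure_terms, "cond")
  if ("hour" %in% structure_terms) out <- c(out, "cond:hour")
  if ("region" %in% structure_terms) out <- c(out, "cond:region")
  out
}

lme_formula <- function(fixed_terms, random) {
  rhs <- if (length(fixed_terms) == 0) "1" else paste(fixed_terms, collapse = " + ")
  stats::as.formula(paste("y ~", rhs, "+", random))
}

fit_ml <- function(data, fixed_terms, random, optimizer = "nloptwrap") {
  ctrl <- lme4::lmerControl(
    optimizer = optimizer, calc.derivs = FALSE,
    check.conv.singular = "ignore", check.conv.grad = "ignore",
    check.conv.hess = "ignore"
  )
  fit <- try(suppressMessages(suppressWarnings(
    lme4::lmer(lme_formula(fixed_terms, random), data = data,
               REML = FALSE, control = ctrl)
  )), silent = TRUE)
  if (inherits(fit, "try-error")) NULL else fit
}

#' Select the supported random-effects structure
#'
#' Starts from the maximal candidate structure (per-mouse intercept and time
#' slope) and falls back to intercept-only when the data do not support the
#' slope: fitted slope variance below `v_tol` ("variance went to zero"),
#' absolute intercept-slope correlation above `c_tol` ("perfectly
#' correlated"), or non-convergence. The intercept is never dropped; data
#' from a single mouse are unidentifiable and yield `NULL` (analyte skipped).
#'
#' When the data pool both brain regions, a per-(mouse, region) series
#' intercept is always included in addition to the mouse terms: every series
#' is standardized against its own baseline window, so all of its z-values
#' share the baseline estimation error as a common offset, and ignoring that
#' offset badly inflates region-involving condition tests.
#'
#' @param data Model data (`y`, `mouse_id`, `hour`, plus fixed covariates).
#' @param fixed_terms Fixed terms used during random-structure evaluation.
#' @param v_tol Variance tolerance (default 1e-6).
#' @param c_tol Correlation tolerance (default 0.99).
#' @return The random-effects formula string, or `NULL` when even the
#'   intercept-only model cannot be fit.
#' @export
select_random_effects <- function(data, fixed_terms, v_tol = 1e-6, c_tol = 0.99) {
  if (length(unique(data$mouse_id)) < 2) return(NULL)
  series_term <- if ("series" %in% names(data) &&
                     nlevels(droplevels(data$series)) > length(unique(data$mouse_id))) {
    " + (1 | series)"
  } else ""
  full <- fit_ml(data, fixed_terms, paste0("(1 + hour | mouse_id)", series_term))
  if (!is.null(full)) {
    vc <- as.data.frame(lme4::VarCorr(full))
    slope_var <- vc$vcov[vc$grp == "mouse_id" & vc$var1 == "hour" & is.na(vc$var2)]
    corr <- vc$sdcor[vc$grp == "mouse_id" & !is.na(vc$var2)]
    slope_ok <- length(slope_var) == 1 && !is.na(slope_var) && slope_var > v_tol
    corr_ok <- length(corr) == 0 || all(!is.na(corr) & abs(corr) < c_tol)
    if (slope_ok && corr_ok) {
      return(paste0("(1 + hour | mouse_id)", series_term))
    }
  }
  base <- fit_ml(data, fixed_terms, paste0("(1 | mouse_id)", series_term))
  if (is.null(base)) NULL else paste0("(1 | mouse_id)", series_term)
}

#' Select fixed effects by AIC among maximum-likelihood fits
#'
#' The Akaike Information Criterion selects the supporting structure of the
#' model - the time trend and region terms - by comparing maximum-likelihood
#' fits of every hierarchy-respecting subset of \{time, region\}, fitted
#' WITHOUT any condition term. The tested full model is then the selected
#' structure plus a deterministic condition block: the condition main effect
#' and its interaction with each structural term present (condition-by-time
#' when time is in the model, condition-by-region when region is). Keeping
#' condition terms out of the selection step entirely is what keeps the
#' subsequent likelihood-ratio test calibrated: letting the criterion look
#' at condition terms - directly or riding along with a structural term -
#' selects the contrasts that happen to look strong and inflates the null
#' rejection rate of the test of those same contrasts to 2-4 times the
#' nominal level.
#'
#' @param data Model data.
#' @param random Random-effects formula string from
#'   [select_random_effects()].
#' @param force_hour Keep the time trend in every candidate (used by the
#'   within-group models, whose condition contrast is a function of time).
#' @return List with `terms` (selected full fixed terms, condition block
#'   included), `structure` (the AIC-selected non-condition terms), `aic`
#'   (of the structure fit), and `aic_table` (every converged candidate), or
#'   `NULL` when no candidate converges.
#' @export
select_fixed_effects <- function(data, random, force_hour = FALSE) {
  cands <- structure_candidate_sets(has_region = length(unique(data$region)) > 1,
                                    force_hour = force_hour)
  aics <- vapply(cands, function(terms) {
    fit <- fit_ml(data, terms, random)
    if (is.null(fit)) NA_real_ else AIC(fit)
  }, numeric(1))
  if (all(is.na(aics))) return(NULL)
  best <- which.min(aics)
  list(terms = with_condition_block(cands[[best]]), structure = cands[[best]],
       aic = aics[best],
       aic_table = tibble::tibble(
         terms = vapply(cands, function(s) paste(sort(s), collapse = "+"), ""),
         aic = aics))
}

# model-implied wake-minus-sleep contrast of the fixed part at a target hour
condition_direction <- function(fit, data, fixed_terms, target_hour,
                                wake_levels, sleep_levels) {
  if (!("cond" %in% fixed_terms)) return(NA_character_)
  lv <- levels(data$cond)
  newdata <- expand.grid(cond = factor(lv, levels = lv), hour = target_hour,
                         region = factor(levels(data$region)[1],
                                         levels = levels(data$region)))
  rhs <- reformulate(if (length(fixed_terms) == 0) "1" else fixed_terms)
  preds <- rowMeans(vapply(levels(data$region), function(r) {
    newdata$region <- factor(r, levels = levels(data$region))
    mm <- model.matrix(rhs, newdata)
    as.numeric(mm %*% lme4::fixef(fit))
  }, numeric(length(lv))))
  wake <- mean(preds[lv %in% wake_levels])
  sleep <- mean(preds[lv %in% sleep_levels])
  if (wake == sleep) return(NA_character_)
  if (wake > sleep) "wake_higher" else "sleep_higher"
}

#' Likelihood-ratio test for the effect of condition
#'
#' Compares the selected full model against a reduced model with every
#' condition-containing term removed (main effect and interactions jointly).
#' The reported effect type is `"interaction"` when the full model carries a
#' condition-by-time interaction (differences between states grow over the
#' experiment) and `"main"` otherwise (a constant state offset). A reduced
#' log-likelihood exceeding the full one beyond tolerance triggers a refit
#' of the full model with an alternative optimizer.
#'
#' The reference distribution depends on the grain of the tested contrast.
#' When condition varies within mice (the within-group phase models) the
#' statistic is referred to the usual chi-squared with `q` degrees of
#' freedom. When condition is constant per mouse (the between-groups model)
#' the chi-squared reference badly understates the uncertainty of a
#' between-mouse contrast estimated from ~19 mice (simulated null rejection
#' around 14% at nominal 5%), so the statistic is rescaled to `stat / q` and
#' referred to an F distribution with a containment-style denominator
#' `ddf = n_mice - 1 - (K - 1)` counting the between-mouse parameters.
#'
#' @param data Model data.
#' @param fixed_terms Selected full fixed terms (condition block included;
#'   see [select_fixed_effects()]).
#' @param random Random-effects formula string.
#' @param ddf Denominator degrees of freedom for the F-scaled reference, or
#'   `NULL` (default) for the chi-squared reference.
#' @return List with `p`, `stat`, `df`, `effect_type` (`"interaction"` /
#'   `"main"`), `fit` (full model), `full_terms`, or `NULL` when fits fail.
#' @export
test_condition <- function(data, fixed_terms, random, ddf = NULL) {
  full_terms <- union(fixed_terms, "cond")
  effect_type <- if ("cond:hour" %in% full_terms) "interaction" else "main"
  reduced_terms <- full_terms[!grepl("cond", full_terms)]
  full <- fit_ml(data, full_terms, random)
  reduced <- fit_ml(data, reduced_terms, random)
  if (is.null(full) || is.null(reduced)) return(NULL)
  if (setequal(full_terms, reduced_terms)) {
    return(list(p = 1, stat = 0, df = 0L, effect_type = effect_type,
                fit = full, full_terms = full_terms))
  }
  stat <- 2 * (as.numeric(logLik(full)) - as.numeric(logLik(reduced)))
  if (stat < -1e-6) {
    refit <- fit_ml(data, full_terms, random, optimizer = "bobyqa")
    if (!is.null(refit) && as.numeric(logLik(refit)) > as.numeric(logLik(full))) {
      full <- refit
      stat <- 2 * (as.numeric(logLik(full)) - as.numeric(logLik(reduced)))
    }
  }
  stat <- max(stat, 0)
  df <- attr(logLik(full), "df") - attr(logLik(reduced), "df")
  if (df <= 0) return(list(p = 1, stat = stat, df = 0L, effect_type = effect_type,
                           fit = full, full_terms = full_terms))
  p <- if (is.null(ddf)) {
    pchisq(stat, df, lower.tail = FALSE)
  } else {
    stats::pf(stat / df, df, ddf, lower.tail = FALSE)
  }
  list(p = p, stat = stat, df = as.integer(df),
       effect_type = effect_type, fit = full, full_terms = full_terms)
}

# assemble the model data for one analyte and one of the three state models.
# Imputed cells are excluded from model fitting: tier-1 cells are copies of
# their condition's mean (feeding them to a condition test counts the same
# evidence twice) and tier-2 cells are within-series interpolations that
# understate residual variance exactly where gaps concentrate (the
# discard-prone contrast windows). Mixed models tolerate the resulting
# missingness natively - the standard reason to use them for repeated
# measures - while the imputed matrix serves the complete-matrix consumers
# (classification, heatmaps, exports).
state_model_data <- function(zm, design, model) {
  if ("provenance" %in% names(zm)) {
    zm <- zm[zm$provenance == "observed", ]
  }
  if (model == "between") {
    x <- dplyr::filter(zm, .data$hour <= 6)
    cond <- design$groups$condition6[match(x$group, design$groups$group)]
    x$cond <- factor(cond, levels = c("S6", "EW6", "SW6"))
  } else {
    grp <- if (model == "within_SEW") "S6_EW3" else "EW6_S3"
    x <- dplyr::filter(zm, .data$group == grp)
    sched <- design$groups$schedule[[match(grp, design$groups$group)]]
    phase <- ifelse(sched[x$hour] == "sleep", "sleep", "wake")
    x$cond <- factor(phase, levels = c("sleep", "wake"))
  }
  x$cond <- droplevels(x$cond)
  tibble::tibble(
    y = x$z, mouse_id = factor(x$mouse_id), cond = x$cond,
    hour = as.numeric(x$hour),
    region = factor(x$region, levels = intersect(c("mPFC", "M1"),
                                                 unique(x$region))),
    series = factor(paste(x$mouse_id, x$region, sep = ":"))
  )
}

# full selection + test machinery for one analyte and one model
run_state_model <- function(data, model) {
  if (nrow(data) == 0 || length(unique(data$cond)) < 2) return(NULL)
  pilot_terms <- c("cond", "hour", "cond:hour")
  if (length(unique(data$region)) > 1) pilot_terms <- c(pilot_terms, "region")
  tr <- choose_transform(data, fixed_terms = pilot_terms)
  data$y <- tr$apply(data$y)
  random <- select_random_effects(data, c("cond", "hour", "cond:hour"))
  if (is.null(random)) return(NULL)
  sel <- select_fixed_effects(data, random, force_hour = model != "between")
  if (is.null(sel)) return(NULL)
  ddf <- if (model == "between") {
    length(unique(data$mouse_id)) - 1L - (nlevels(data$cond) - 1L)
  } else {
    NULL    # phase contrasts are within-mouse; chi-squared is calibrated
  }
  tst <- test_condition(data, sel$terms, random, ddf = ddf)
  if (is.null(tst)) return(NULL)
  target_hour <- if (model == "between") 6 else 9
  # direction is a trajectory-consistency check, so it is read from the
  # descriptive interaction model rather than the AIC-parsimonious one: a
  # main-effects-only fit of a rise-then-fall profile places the sleep phase
  # at the trajectory peak and misstates which state is higher
  desc <- fit_ml(data, pilot_terms, random)
  dir_fit <- if (is.null(desc)) tst$fit else desc
  dir_terms <- if (is.null(desc)) tst$full_terms else pilot_terms
  dir <- condition_direction(dir_fit, data, dir_terms, target_hour,
                             wake_levels = c("EW6", "SW6", "wake"),
                             sleep_levels = c("S6", "sleep"))
  list(p = tst$p, effect_type = tst$effect_type, direction = dir,
       transform = tr$name, random = random,
       selected_terms = paste(sort(sel$terms), collapse = "+"),
       aic = sel$aic, stat = tst$stat, df = tst$df)
}

#' State-specificity verdict from the three model results
#'
#' An analyte is state-specific when at least one of the three models
#' (between-groups, within sleep-then-wake, within wake-then-sleep) is
#' significant at `alpha` and all three model-implied directions agree
#' (all wake-higher or all sleep-higher). A compound that is significant in
#' one model but moves the opposite way in another is rejected; an analyte
#' with any failed model is undetermined.
#'
#' @param p Numeric vector of the three p-values.
#' @param direction Character vector of the three directions
#'   (`"wake_higher"` / `"sleep_higher"`).
#' @param alpha Significance level (default 0.05).
#' @return `TRUE`, `FALSE`, or `NA` (undetermined: a model was skipped or
#'   produced no direction).
#' @export
state_specificity <- function(p, direction, alpha = 0.05) {
  if (any(is.na(p)) || any(is.na(direction))) return(NA)
  any(p < alpha) && length(unique(direction)) == 1
}

#' Three-model mixed-effects state tests for every analyte
#'
#' For each analyte runs the full model-selection and likelihood-ratio
#' machinery three times: the between-groups model (hours 1-6, all arms,
#' condition = dominant first-6-h state), and the two within-group models
#' (hours 1-9 of the sleep-then-wake and wake-then-sleep arms, condition =
#' behavioral phase). Each run selects the response transform, the supported
#' random structure and the minimum-AIC fixed structure, then tests the
#' condition effect by likelihood ratio and reports the model-implied
#' direction at the end of the modeled window (hour 6 between-groups, hour 9
#' within-group). Verdicts follow [state_specificity()].
#'
#' @param zm Imputed z-matrix tibble from [preprocess_cohort()].
#' @param design A [study_design()].
#' @param alpha Significance level (default 0.05).
#' @param analytes Optional subset of analyte ids.
#' @return Tibble with one row per analyte: three p-values, effect types,
#'   directions, transforms, selected terms, and `state_specific`.
#' @export
analyte_state_tests <- function(zm, design, alpha = 0.05, analytes = NULL) {
  ids <- if (is.null(analytes)) sort(unique(zm$analyte_id)) else analytes
  models <- c("between", "within_SEW", "within_EWS")
  purrr::map_dfr(ids, function(a) {
    za <- zm[zm$analyte_id == a, ]
    res <- lapply(models, function(m) {
      run_state_model(state_model_data(za, design, m), m)
    })
    get <- function(i, f, default = NA) {
      if (is.null(res[[i]])) default else res[[i]][[f]]
    }
    p <- c(get(1, "p", NA_real_), get(2, "p", NA_real_), get(3, "p", NA_real_))
    dir <- c(get(1, "direction", NA_character_), get(2, "direction", NA_character_),
             get(3, "direction", NA_character_))
    tibble::tibble(
      analyte_id = a,
      p_between = p[1], p_within_SEW = p[2], p_within_EWS = p[3],
      effect_between = get(1, "effect_type", NA_character_),
      effect_within_SEW = get(2, "effect_type", NA_character_),
      effect_within_EWS = get(3, "effect_type", NA_character_),
      dir_between = dir[1], dir_within_SEW = dir[2], dir_within_EWS = dir[3],
      transform_between = get(1, "transform", NA_character_),
      state_specific = state_specificity(p, dir, alpha)
    )
  })
}

#' Sleep-phase model: early vs late vs recovery sleep
#'
#' Compares the trend of an analyte across three sleep windows: early sleep
#' (hours 1-3 of the sleep-first arm), late sleep (hours 4-6 of the same
#' arm) and recovery sleep (hours 7-9 of the wake-first arm, following
#' enforced wakefulness). Time is recoded 1-3 within each window. The model
#' is `y ~ sleep_condition * time + (1 | mouse)` by maximum likelihood; the
#' interaction is tested by likelihood ratio against
#' `y ~ sleep_condition + time` (2 df), and per-condition time slopes are
#' read off the fixed effects. The early-vs-recovery slope contrast is a
#' Wald z-test on the recovery:time interaction coefficient, uncorrected.
#'
#' @param zm Imputed z-matrix for one analyte.
#' @param design A [study_design()].
#' @param region Brain region to analyze.
#' @return List with `p_interaction`, `slopes` (named: early, late,
#'   recovery), `contrast_p` (early vs recovery) and `fit`, or `NULL` when
#'   the windows are absent or the fit fails.
#' @export
sleep_phase_model <- function(zm, design, region) {
  if ("provenance" %in% names(zm)) {
    zm <- zm[zm$provenance == "observed", ]   # see state_model_data
  }
  x <- zm[zm$region == region, ]
  early <- x[x$group == "S6_EW3" & x$hour %in% 1:3, ]
  late <- x[x$group == "S6_EW3" & x$hour %in% 4:6, ]
  rec <- x[x$group == "EW6_S3" & x$hour %in% 7:9, ]
  if (nrow(early) == 0 || nrow(late) == 0 || nrow(rec) == 0) return(NULL)
  data <- tibble::tibble(
    y = c(early$z, late$z, rec$z),
    mouse_id = factor(c(early$mouse_id, late$mouse_id, rec$mouse_id)),
    cond = factor(rep(c("early", "late", "recovery"),
                      c(nrow(early), nrow(late), nrow(rec))),
                  levels = c("early", "late", "recovery")),
    time = c(early$hour, late$hour - 3, rec$hour - 6)
  )
  tr <- choose_transform(data, c("cond", "time", "cond:time"))
  data$y <- tr$apply(data$y)
  full <- fit_ml(data, c("cond", "time", "cond:time"), "(1 | mouse_id)")
  reduced <- fit_ml(data, c("cond", "time"), "(1 | mouse_id)")
  if (is.null(full) || is.null(reduced)) return(NULL)
  stat <- max(0, 2 * (as.numeric(logLik(full)) - as.numeric(logLik(reduced))))
  df <- attr(logLik(full), "df") - attr(logLik(reduced), "df")
  p_int <- pchisq(stat, df, lower.tail = FALSE)
  fe <- lme4::fixef(full)
  slopes <- c(
    early = unname(fe["time"]),
    late = unname(fe["time"] + fe["condlate:time"]),
    recovery = unname(fe["time"] + fe["condrecovery:time"])
  )
  vc <- vcov(full)
  b <- fe["condrecovery:time"]
  se <- sqrt(vc["condrecovery:time", "condrecovery:time"])
  contrast_p <- 2 * pnorm(-abs(b / se))
  list(p_interaction = p_int, slopes = slopes, contrast_p = unname(contrast_p),
       transform = tr$name, fit = full)
}

#' Classify the sleep-decline pattern of an analyte
#'
#' Applies the three-way typing of sleep-decline dynamics: with a
#' significant sleep-condition-by-time interaction and both early and
#' recovery slopes negative, the analyte is Type 1 when the early and
#' recovery slopes do not differ significantly, Type 2 when recovery sleep
#' declines significantly faster than early sleep, and Type 3 when early
#' sleep declines significantly faster. When either compared slope is
#' non-negative the pattern is "other"; without a significant interaction no
#' type is assigned (`NA`).
#'
#' @param slopes Named numeric vector with `early` and `recovery` slopes.
#' @param contrast_p Wald p-value of the early-vs-recovery slope contrast.
#' @param p_interaction Interaction p-value from [sleep_phase_model()].
#' @param alpha Significance level (default 0.05).
#' @return `"Type1"`, `"Type2"`, `"Type3"`, `"other"`, or `NA_character_`.
#' @export
classify_sleep_pattern <- function(slopes, contrast_p, p_interaction, alpha = 0.05) {
  if (is.na(p_interaction) || p_interaction >= alpha) return(NA_character_)
  if (!(slopes["early"] < 0 && slopes["recovery"] < 0)) return("other")
  if (contrast_p >= alpha) return("Type1")
  if (slopes["recovery"] < slopes["early"]) "Type2" else "Type3"
}

#' Sleep-phase typing report for all analytes and regions
#'
#' Runs [sleep_phase_model()] and [classify_sleep_pattern()] per analyte and
#' region.
#'
#' @param zm Imputed z-matrix tibble.
#' @param design A [study_design()].
#' @param alpha Significance level (default 0.05).
#' @return Tibble with `analyte_id`, `region`, `p_interaction`, the three
#'   slopes, `contrast_p` and `pattern`.
#' @export
sleep_phase_report <- function(zm, design, alpha = 0.05) {
  grid <- dplyr::distinct(zm, .data$analyte_id, .data$region)
  purrr::map_dfr(seq_len(nrow(grid)), function(i) {
    a <- grid$analyte_id[i]; r <- grid$region[i]
    res <- sleep_phase_model(zm[zm$analyte_id == a, ], design, r)
    if (is.null(res)) {
      return(tibble::tibble(analyte_id = a, region = r,
                            p_interaction = NA_real_, slope_early = NA_real_,
                            slope_late = NA_real_, slope_recovery = NA_real_,
                            contrast_p = NA_real_, pattern = NA_character_))
    }
    tibble::tibble(
      analyte_id = a, region = r, p_interaction = res$p_interaction,
      slope_early = res$slopes["early"], slope_late = res$slopes["late"],
      slope_recovery = res$slopes["recovery"], contrast_p = res$contrast_p,
      pattern = classify_sleep_pattern(res$slopes, res$contrast_p,
                                       res$p_interaction, alpha)
    )
  })
}
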