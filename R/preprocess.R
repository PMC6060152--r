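#' Detection filter: analytes observed in enough mice of every arm
#'
#' An analyte is retained in a region only if, in every experimental arm, it
#' has at least one non-missing observation in at least `min_mice` mice. The
#' criterion is applied separately per brain region, so an analyte may be
#' retained in one region only.
#'
#' @param table Long intensity table (see [validate_long_table()]).
#' @param design A [study_design()].
#' @param min_mice Minimum number of mice per arm (default 3).
#' @return Tibble of retained (`region`, `analyte_id`) pairs.
#' @export
detection_filter <- function(table, design, min_mice = 3L) {
  if (min_mice > min(design$groups$n_mice)) {
    stop("parameter error: min_mice exceeds the smallest arm size")
  }
  obs <- dplyr::filter(table, !is.na(.data$intensity))
  counts <- dplyr::distinct(obs, .data$region, .data$analyte_id, .data$group,
                            .data$mouse_id)
  counts <- dplyr::count(counts, .data$region, .data$analyte_id, .data$group,
                         name = "n_mice_obs")
  full <- tidyr::expand_grid(
    dplyr::distinct(table, .data$region, .data$analyte_id),
    group = design$groups$group
  )
  counts <- dplyr::left_join(full, counts, by = c("region", "analyte_id", "group"))
  counts$n_mice_obs[is.na(counts$n_mice_obs)] <- 0L
  keep <- dplyr::summarise(
    dplyr::group_by(counts, .data$region, .data$analyte_id),
    ok = all(.data$n_mice_obs >= min_mice), .groups = "drop"
  )
  dplyr::select(dplyr::filter(keep, .data$ok), "region", "analyte_id")
}

#' Baseline z-scoring against the reference window
#'
#' Standardizes each (mouse, region, analyte) series by the mean and standard
#' deviation of its own reference-window samples, separately for every mouse,
#' brain region and analyte. Series with fewer than two non-missing reference
#' values, or with zero reference standard deviation, cannot be standardized
#' and are dropped with a logged reason. Series with no observation at all
#' (an analyte completely absent from a sample) are not dropped: they pass
#' through as all-missing and are later filled by tier-1 imputation.
#'
#' @param table Long intensity table.
#' @param design A [study_design()].
#' @return List with `z` (long table with a `z` column replacing `intensity`),
#'   `baseline_stats` (per-series `mu`, `sigma`, `n_ref`), and `dropped`
#'   (series removed, with `reason`).
#' @export
baseline_zscore <- function(table, design) {
  ref <- reference_bins(design)
  key <- c("mouse_id", "group", "region", "analyte_id")
  stats_tbl <- dplyr::summarise(
    dplyr::group_by(table, dplyr::across(dplyr::all_of(key))),
    n_total = sum(!is.na(.data$intensity)),
    n_ref = sum(.data$bin_index %in% ref & !is.na(.data$intensity)),
    mu = mean(.data$intensity[.data$bin_index %in% ref], na.rm = TRUE),
    sigma = stats::sd(.data$intensity[.data$bin_index %in% ref], na.rm = TRUE),
    .groups = "drop"
  )
  stats_tbl$reason <- dplyr::case_when(
    stats_tbl$n_total == 0 ~ NA_character_,   # empty series: keep for tier-1
    stats_tbl$n_ref < 2 ~ "fewer than 2 reference observations",
    !is.na(stats_tbl$sigma) & stats_tbl$sigma == 0 ~ "zero reference standard deviation",
    TRUE ~ NA_character_
  )
  dropped <- dplyr::filter(stats_tbl, !is.na(.data$reason))
  kept <- dplyr::filter(stats_tbl, is.na(.data$reason))
  z <- dplyr::inner_join(table, kept[c(key, "n_total", "mu", "sigma")], by = key)
  z$z <- (z$intensity - z$mu) / z$sigma
  z$z[z$n_total == 0] <- NA_real_
  z <- z[c(key, "bin_index", "z")]
  usable <- dplyr::filter(kept, .data$n_total > 0)
  list(z = z, baseline_stats = usable[c(key, "n_ref", "mu", "sigma")],
       dropped = dropped[c(key, "reason")])
}

#' Flag single-sample outliers in one z-score series
#'
#' An observation is an outlier if its absolute z-score is more than `factor`
#' times greater than every other absolute z-score of the same series.
#' Absolute values make the rule symmetric for analytes that move below
#' baseline.
#'
#' @param z Numeric vector of z-scores (may contain `NA`).
#' @param factor Multiplier (default 5).
#' @return Integer vector of flagged positions in `z`.
#' @export
flag_outlier_series <- function(z, factor = 5) {
  obs <- which(!is.na(z))
  if (length(obs) < 2) {
    if (length(obs) == 1) warning("series has a single observation; no outlier flags")
    return(integer(0))
  }
  a <- abs(z[obs])
  ord <- order(a, decreasing = TRUE)
  top1 <- a[ord[1]]; top2 <- a[ord[2]]
  max_other <- ifelse(seq_along(a) == ord[1], top2, top1)
  obs[a > factor * max_other]
}

#' Flag and blank outliers across all series of a z table
#'
#' Applies [flag_outlier_series()] per (mouse, region, analyte) series and
#' sets flagged entries to missing.
#'
#' @param ztbl Long z-score table from [baseline_zscore()].
#' @param factor Multiplier (default 5).
#' @return List with `z` (flagged entries blanked) and `flags` (coordinates of
#'   flagged observations).
#' @export
flag_outliers <- function(ztbl, factor = 5) {
  key <- c("mouse_id", "region", "analyte_id")
  ztbl <- dplyr::arrange(ztbl, dplyr::across(dplyr::all_of(c(key, "bin_index"))))
  idx <- unlist(lapply(
    split(seq_len(nrow(ztbl)), ztbl[key], drop = TRUE),
    function(rows) rows[flag_outlier_series(ztbl$z[rows], factor)]
  ), use.names = FALSE)
  flags <- ztbl[idx, c(key, "bin_index", "z")]
  ztbl$z[idx] <- NA_real_
  list(z = ztbl, flags = flags)
}

#' Discard samples collected in the wrong behavioral state
#'
#' A bin is discarded when the observed wake fraction contradicts the arm's
#' scheduled state by strictly more than `threshold`: scheduled sleep with
#' more than `threshold` of the bin awake, or scheduled wake with more than
#' `threshold` asleep. A bin at exactly the threshold is retained.
#'
#' @param table Long table with `mouse_id`, `group`, `bin_index` (z or raw).
#' @param wake Wake-fraction table.
#' @param design A [study_design()].
#' @param threshold Contradiction threshold (default 0.5).
#' @return List with `table` (offending rows removed) and `discarded`
#'   (distinct (mouse, bin) pairs removed).
#' @export
wrong_state_filter <- function(table, wake, design, threshold = 0.5) {
  sched <- scheduled_states(design)[c("group", "bin_index", "sched_state")]
  x <- dplyr::left_join(table, wake, by = c("mouse_id", "bin_index"))
  if (any(is.na(x$wake_fraction))) {
    stop_integrity("missing wake fraction for some (mouse, bin) present in the table")
  }
  x <- dplyr::left_join(x, sched, by = c("group", "bin_index"))
  bad <- (x$sched_state == "sleep" & x$wake_fraction > threshold) |
    (x$sched_state == "wake" & (1 - x$wake_fraction) > threshold)
  discarded <- dplyr::distinct(x[bad, ], .data$mouse_id, .data$bin_index)
  out <- x[!bad, names(table)]
  list(table = out, discarded = discarded)
}

#' Coarse-grain 15-min z-scores to hourly values
#'
#' Post-reference bins are averaged in consecutive blocks of
#' `design$coarse_factor` (4 bins = 1 hour). An hourly value is the mean of
#' its non-missing members and is missing only when all members are missing
#' or were removed upstream. Reference bins are not part of any hour.
#'
#' @param ztbl Long z table (15-min resolution), possibly with rows removed.
#' @param design A [study_design()].
#' @return A z-matrix tibble: one row per (mouse, group, region, analyte,
#'   hour) on the complete grid of series present in `ztbl`, with `z` (`NA`
#'   when missing), `n_obs` (contributing bins) and `provenance`
#'   (`"observed"` / `"missing"`).
#' @export
coarse_grain <- function(ztbl, design) {
  key <- c("mouse_id", "group", "region", "analyte_id")
  x <- dplyr::filter(ztbl, .data$bin_index >= design$n_reference)
  x$hour <- hour_of_bin(design, x$bin_index)
  hourly <- dplyr::summarise(
    dplyr::group_by(x, dplyr::across(dplyr::all_of(c(key, "hour")))),
    n_obs = sum(!is.na(.data$z)),     # before z is overwritten below
    z = if (all(is.na(.data$z))) NA_real_ else mean(.data$z, na.rm = TRUE),
    .groups = "drop"
  )
  grid <- tidyr::expand_grid(dplyr::distinct(ztbl[key]),
                             hour = seq_len(design$n_hours))
  zm <- dplyr::left_join(grid, hourly, by = c(key, "hour"))
  zm$n_obs[is.na(zm$n_obs)] <- 0L
  zm$provenance <- ifelse(is.na(zm$z), "missing", "observed")
  dplyr::arrange(zm, dplyr::across(dplyr::all_of(c(key, "hour"))))
}

# mean of the k nearest observed hours (ties broken toward earlier hours);
# fewer than k observed hours use all of them (a single one is copied)
impute_point <- function(hour, obs_hours, obs_values, k = 2L) {
  d <- abs(obs_hours - hour)
  ord <- order(d, obs_hours)
  mean(obs_values[ord[seq_len(min(k, length(ord)))]])
}

#' Two-tier imputation of an hourly z-matrix
#'
#' Tier 1: a series (mouse, region, analyte) with no observed hour receives,
#' at every hour, the mean observed z across the other mice of the same arm
#' for the same region, analyte and hour. Tier 2: remaining point gaps in
#' series with at least one observed hour receive the mean of the two nearest
#' observed hours of the same series (both from one side at the edges; a
#' single observed hour is copied). Tier-2 neighbors are restricted to
#' originally observed hours so imputations are never chained. Provenance is
#' recorded per cell and no missing entries remain.
#'
#' @param zm Z-matrix tibble from [coarse_grain()].
#' @param knn_k Number of nearest observed hours averaged in tier 2
#'   (default 2).
#' @return `zm` with all `z` filled and `provenance` updated to
#'   `"imputed_tier1"` / `"imputed_tier2"` where applicable.
#' @export
impute_zmatrix <- function(zm, knn_k = 2L) {
  key <- c("mouse_id", "region", "analyte_id")
  zm <- dplyr::arrange(zm, dplyr::across(dplyr::all_of(c(key, "hour"))))
  series <- split(seq_len(nrow(zm)), zm[key], drop = TRUE)
  n_obs_per_series <- vapply(series, function(r) sum(!is.na(zm$z[r])), 0L)

  # tier 1: cross-mouse condition means for entirely missing series
  empty <- names(series)[n_obs_per_series == 0]
  if (length(empty) > 0) {
    donors <- dplyr::summarise(
      dplyr::group_by(zm[zm$provenance == "observed", ],
                      .data$group, .data$region, .data$analyte_id, .data$hour),
      donor_mean = mean(.data$z), n_donors = dplyr::n(), .groups = "drop"
    )
    rows <- unlist(series[empty], use.names = FALSE)
    fill <- dplyr::left_join(
      zm[rows, c("group", "region", "analyte_id", "hour")], donors,
      by = c("group", "region", "analyte_id", "hour")
    )
    if (any(is.na(fill$donor_mean))) {
      bad <- zm[rows[is.na(fill$donor_mean)],
                c("mouse_id", "group", "region", "analyte_id", "hour")]
      stop_integrity(
        "cells imputable by neither tier: ",
        paste(utils::capture.output(print(as.data.frame(utils::head(bad, 5)))),
              collapse = "\n")
      )
    }
    zm$z[rows] <- fill$donor_mean
    zm$provenance[rows] <- "imputed_tier1"
  }

  # tier 2: nearest-neighbor hours within partially observed series
  partial <- names(series)[n_obs_per_series > 0]
  for (s in partial) {
    rows <- series[[s]]
    obs <- zm$provenance[rows] == "observed"
    gap <- is.na(zm$z[rows])
    if (!any(gap)) next
    oh <- zm$hour[rows][obs]; ov <- zm$z[rows][obs]
    zm$z[rows][gap] <- vapply(zm$hour[rows][gap], impute_point,
                              numeric(1), obs_hours = oh, obs_values = ov,
                              k = knn_k)
    zm$provenance[rows][gap] <- "imputed_tier2"
  }
  zm
}

#' Pairwise group-difference matrix of hourly z-scores
#'
#' For two experimental arms and one brain region, computes the analyte-by-
#' hour matrix of differences in mean z (mean over mice of `group_a` minus
#' mean over mice of `group_b`), the quantity displayed in hour-resolved
#' pairwise heatmaps.
#'
#' @param zm (Imputed) z-matrix tibble.
#' @param group_a,group_b Arm names.
#' @param region Brain region.
#' @param hours Hours to include (default 1-6).
#' @return Numeric matrix, analytes in rows, hours in columns.
#' @export
heatmap_matrix <- function(zm, group_a, group_b, region, hours = 1:6) {
  x <- dplyr::filter(zm, .data$region == !!region, .data$hour %in% hours,
                     .data$group %in% c(group_a, group_b))
  shared <- intersect(unique(x$analyte_id[x$group == group_a]),
                      unique(x$analyte_id[x$group == group_b]))
  if (length(shared) == 0) stop("groups share no analytes in region ", region)
  x <- dplyr::filter(x, .data$analyte_id %in% shared)
  means <- dplyr::summarise(
    dplyr::group_by(x, .data$analyte_id, .data$hour, .data$group),
    m = mean(.data$z, na.rm = TRUE), .groups = "drop"
  )
  wide <- tidyr::pivot_wider(means, names_from = "group", values_from = "m")
  wide$delta <- wide[[group_a]] - wide[[group_b]]
  out <- tidyr::pivot_wider(wide[c("analyte_id", "hour", "delta")],
                            names_from = "hour", values_from = "delta")
  m <- as.matrix(out[, -1])
  rownames(m) <- out$analyte_id
  m[, order(as.integer(colnames(m))), drop = FALSE]
}

#' Run the full preprocessing ladder on a cohort
#'
#' Applies, in order: the detection filter, baseline z-scoring, the 5x
#' outlier rule on 15-min z-series, the wrong-state sample exclusion, hourly
#' coarse-graining, and two-tier imputation, and assembles an audit of every
#' count the ladder produces.
#'
#' @param samples Long intensity table.
#' @param wake Wake-fraction table.
#' @param design A [study_design()].
#' @param min_mice Detection threshold (default 3).
#' @param outlier_factor Outlier rule multiplier (default 5).
#' @param wrong_state_threshold Wrong-state threshold (default 0.5).
#' @param knn_k Tier-2 neighbor count (default 2).
#' @return List with `zmatrix` (complete, imputed), `zmatrix_raw` (pre-
#'   imputation), `retained` analyte-region pairs, `baseline_stats`,
#'   `dropped_series`, `outlier_flags`, `discarded_bins`, and `audit` (named
#'   list of counts, including imputed cells by tier and the imputed
#'   fraction of the hourly grid).
#' @export
preprocess_cohort <- function(samples, wake, design,
                              min_mice = 3L, outlier_factor = 5,
                              wrong_state_threshold = 0.5, knn_k = 2L) {
  samples <- validate_long_table(samples, design)
  wake <- validate_wake_table(wake, design)
  retained <- detection_filter(samples, design, min_mice)
  kept <- dplyr::inner_join(samples, retained, by = c("region", "analyte_id"))
  zs <- baseline_zscore(kept, design)
  fl <- flag_outliers(zs$z, outlier_factor)
  ws <- wrong_state_filter(fl$z, wake, design, wrong_state_threshold)
  zm_raw <- coarse_grain(ws$table, design)
  zm <- impute_zmatrix(zm_raw, knn_k = knn_k)
  n_cells <- nrow(zm)
  audit <- list(
    n_analytes_retained = nrow(retained),
    n_series_dropped = nrow(zs$dropped),
    n_outliers_flagged = nrow(fl$flags),
    n_bins_discarded = nrow(ws$discarded),
    n_imputed_tier1 = sum(zm$provenance == "imputed_tier1"),
    n_imputed_tier2 = sum(zm$provenance == "imputed_tier2"),
    n_cells = n_cells,
    imputed_fraction = sum(zm$provenance != "observed") / n_cells
  )
  list(zmatrix = zm, zmatrix_raw = zm_raw, retained = retained,
       baseline_stats = zs$baseline_stats, dropped_series = zs$dropped,
       outlier_flags = fl$flags, discarded_bins = ws$discarded, audit = audit)
}
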