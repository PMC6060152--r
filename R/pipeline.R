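#' Run the full analysis pipeline from a configuration
#'
#' Chains the pipeline stages on file inputs: preprocessing (detection
#' filter, baseline z-scoring, outlier rule, wrong-state exclusion,
#' coarse-graining, imputation), unknown-feature clustering (when a feature
#' table is configured), per-analyte mixed-effects state tests and
#' sleep-phase typing, classification with cross-validated and
#' permutation-tested accuracy, and EEG band correlations (when a band-power
#' table is configured; otherwise that stage is skipped with a warning).
#' Per-stage TSV outputs and a JSON summary are written to `out_dir`. With a
#' fixed configuration and seed the outputs are identical across runs.
#'
#' @param config A configuration list (see [default_config()]) or the path
#'   to a YAML file readable by [read_run_config()].
#' @param out_dir Output directory (created if absent).
#' @param design A [study_design()]; when `NULL`, built from the `design`
#'   block of the configuration (or the package default layout).
#' @return The summary list, invisibly. Stage failures abort with a
#'   stage-tagged message.
#' @export
run_pipeline <- function(config, out_dir, design = NULL) {
  if (is.character(config)) config <- read_run_config(config)
  if (is.null(design)) {
    design <- if (is.null(config$design)) study_design() else {
      do.call(study_design, c(
        if (!is.null(config$design$n_mice_per_group)) {
          list(n_mice_per_group = unlist(config$design$n_mice_per_group))
        },
        if (!is.null(config$design$regions)) {
          list(regions = unlist(config$design$regions))
        }
      ))
    }
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("stage [", name, "] failed: ", conditionMessage(e), call. = FALSE)
    })
  }
  summary <- list(seed = config$seed)

  samples <- stage("read", read_long_table(config$inputs$samples, design))
  wake <- stage("read", read_wake_table(config$inputs$wake, design))

  pp <- stage("preprocess", preprocess_cohort(
    samples, wake, design, min_mice = config$min_mice,
    outlier_factor = config$outlier_factor,
    wrong_state_threshold = config$wrong_state_threshold,
    knn_k = config$knn_k
  ))
  readr::write_tsv(pp$zmatrix, file.path(out_dir, "zmatrix.tsv"), na = "")
  readr::write_tsv(pp$outlier_flags, file.path(out_dir, "outliers.tsv"), na = "")
  summary$preprocess <- pp$audit

  if (!is.null(config$inputs$features)) {
    features <- stage("cluster", read_feature_table(config$inputs$features, design))
    unk <- stage("cluster", unknown_feature_report(
      features, wake, design, mass_tol = config$mass_tol,
      rt_tol = config$rt_tol, min_mice = config$min_mice,
      alpha = config$alpha
    ))
    readr::write_tsv(unk, file.path(out_dir, "unknown_features.tsv"), na = "")
    summary$clustering <- list(
      n_clusters_tested = nrow(unk),
      n_state_specific = sum(unk$state_specific %in% TRUE)
    )
  } else {
    summary$clustering <- list(n_clusters_tested = 0L, n_state_specific = 0L)
  }

  verdicts <- stage("lme", analyte_state_tests(pp$zmatrix, design,
                                               alpha = config$alpha))
  readr::write_tsv(verdicts, file.path(out_dir, "state_tests.tsv"), na = "")
  phases <- stage("lme", sleep_phase_report(pp$zmatrix, design,
                                            alpha = config$alpha))
  readr::write_tsv(phases, file.path(out_dir, "sleep_phase.tsv"), na = "")
  summary$lme <- list(
    n_analytes = nrow(verdicts),
    n_state_specific = sum(verdicts$state_specific %in% TRUE),
    n_typed = sum(!is.na(phases$pattern))
  )

  fm <- stage("classification", build_feature_matrix(pp$zmatrix, design))
  pt <- stage("classification", permutation_test(
    fm$X, fm$y, fm$mouse, K = config$cv_folds, C = config$C,
    n_permutations = config$n_permutations,
    reps_observed = config$cv_reps, reps_perm = config$perm_cv_reps,
    seed = config$seed
  ))
  readr::write_tsv(
    tibble::tibble(repetition = seq_along(pt$observed$accuracies),
                   accuracy = pt$observed$accuracies),
    file.path(out_dir, "cv_accuracies.tsv")
  )
  pls <- stage("classification", fit_plsda(fm$X, fm$y, ncomp = 2))
  vip <- sort(vip_scores(pls), decreasing = TRUE)
  readr::write_tsv(
    tibble::tibble(feature = names(vip), vip = unname(vip),
                   rank = seq_along(vip)),
    file.path(out_dir, "vip_scores.tsv")
  )
  summary$classification <- list(
    accuracy_3way = pt$observed$mean_accuracy,
    ci_3way = pt$observed$ci,
    p_3way = pt$p,
    mean_permuted_accuracy = pt$mean_perm_accuracy,
    n_vip_above_1 = sum(vip > 1)
  )

  if (!is.null(config$inputs$bands)) {
    bands <- stage("correlation", read_band_table(config$inputs$bands, design))
    recs <- stage("correlation", dplyr::bind_rows(
      bh_correct(correlate_band(pp$zmatrix, bands, design, "low_2_6"),
                 config$fdr_q),
      bh_correct(correlate_band(pp$zmatrix, bands, design, "swa_0p5_4"),
                 config$fdr_q),
      gamma_null_check(pp$zmatrix, bands, design, q = config$fdr_q)
    ))
    readr::write_tsv(recs, file.path(out_dir, "eeg_correlations.tsv"), na = "")
    summary$correlation <- list(
      n_tests = sum(!is.na(recs$p)),
      n_pass = sum(recs$q_pass %in% TRUE),
      n_pass_gamma = sum(recs$q_pass[recs$band == "gamma_40_100"] %in% TRUE)
    )
  } else {
    warning("no EEG band-power table configured; correlation stage skipped")
    summary$correlation <- NULL
  }

  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(summary)
}
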