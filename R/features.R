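#' Cluster unknown spectral features by exact mass and retention time
#'
#' Two feature observations measure the same unknown compound when their
#' parent masses differ by strictly less than `mass_tol` Daltons and their
#' retention times by strictly less than `rt_tol` minutes. Because this
#' pairwise relation is not transitive, features are partitioned by its
#' transitive closure (single linkage): any two members of a cluster are
#' connected by a chain of tolerance-respecting pairs. Each cluster is
#' summarized by its median mass and retention time, which are robust to a
#' stray tail feature.
#'
#' @param features Feature table with `mass`, `rt` columns (plus any sample
#'   columns, carried through).
#' @param mass_tol Mass tolerance in Daltons (default 0.0014).
#' @param rt_tol Retention-time tolerance in minutes (default 0.3).
#' @return List with `features` (input plus `cluster_id`) and `clusters`
#'   (per-cluster `cluster_id`, `median_mass`, `median_rt`, `n_features`),
#'   clusters labelled in order of increasing median mass.
#' @export
cluster_features <- function(features, mass_tol = 0.0014, rt_tol = 0.3) {
  if (mass_tol <= 0 || rt_tol <= 0) stop("tolerances must be positive")
  n <- nrow(features)
  if (n == 0) {
    features$cluster_id <- character(0)
    return(list(features = features,
                clusters = tibble::tibble(cluster_id = character(),
                                          median_mass = numeric(),
                                          median_rt = numeric(),
                                          n_features = integer())))
  }
  comp <- single_linkage_components(features$mass, features$rt, mass_tol, rt_tol)
  summ <- tibble::tibble(comp = comp, mass = features$mass, rt = features$rt)
  summ <- dplyr::summarise(dplyr::group_by(summ, .data$comp),
                           median_mass = stats::median(.data$mass),
                           median_rt = stats::median(.data$rt),
                           n_features = dplyr::n(), .groups = "drop")
  summ <- dplyr::arrange(summ, .data$median_mass, .data$median_rt)
  summ$cluster_id <- sprintf("F%04d", seq_len(nrow(summ)))
  features$cluster_id <- summ$cluster_id[match(comp, summ$comp)]
  list(features = features,
       clusters = summ[c("cluster_id", "median_mass", "median_rt", "n_features")])
}

# connected components of the tolerance graph, without materializing all
# pairs: features are sorted by mass, so only a sliding mass window needs
# pairwise testing; components are merged with union-find
single_linkage_components <- function(mass, rt, mass_tol, rt_tol) {
  n <- length(mass)
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  ord <- order(mass)
  lo <- 1L
  for (k in seq_len(n)) {
    i <- ord[k]
    while (mass[i] - mass[ord[lo]] >= mass_tol) lo <- lo + 1L
    if (lo < k) {
      for (j in ord[lo:(k - 1L)]) {
        if (abs(mass[i] - mass[j]) < mass_tol && abs(rt[i] - rt[j]) < rt_tol) {
          ri <- find(i); rj <- find(j)
          if (ri != rj) parent[ri] <- rj
        }
      }
    }
  }
  vapply(seq_len(n), find, integer(1))
}

#' Collapse clustered features into a long intensity table
#'
#' Emits one row per (mouse, region, cluster, bin). When a cluster has
#' several feature observations in the same sample (jitter duplicates), the
#' most intense one is kept.
#'
#' @param clustered Result of [cluster_features()] on a feature table that
#'   carries `mouse_id`, `group`, `region`, `bin_index`, `intensity`.
#' @return A long intensity table with `analyte_id` = cluster id, suitable
#'   for [preprocess_cohort()]. Bins where a cluster was not detected are
#'   absent (missing).
#' @export
features_to_long_table <- function(clustered) {
  x <- clustered$features
  x <- dplyr::summarise(
    dplyr::group_by(x, .data$mouse_id, .data$group, .data$region,
                    .data$cluster_id, .data$bin_index),
    intensity = max(.data$intensity), .groups = "drop"
  )
  dplyr::rename(x, analyte_id = "cluster_id")
}

#' State-specificity report for unknown spectral features
#'
#' Clusters a feature table, converts clusters to a long intensity table on
#' the complete design grid (undetected bins become missing), and runs the
#' identical preprocessing and three-model mixed-effects machinery used for
#' known analytes. The report is keyed by each cluster's median mass and
#' retention time.
#'
#' @param features Feature observation table.
#' @param wake Wake-fraction table.
#' @param design A [study_design()].
#' @param mass_tol,rt_tol Clustering tolerances.
#' @param min_mice Detection threshold.
#' @param alpha Significance level for the state-specificity verdict.
#' @return Tibble with `median_mass`, `median_rt`, the three model p-values,
#'   directions and the `state_specific` verdict (columns as in
#'   [analyte_state_tests()]).
#' @export
unknown_feature_report <- function(features, wake, design,
                                   mass_tol = 0.0014, rt_tol = 0.3,
                                   min_mice = 3L, alpha = 0.05) {
  cl <- cluster_features(features, mass_tol, rt_tol)
  if (nrow(cl$clusters) == 0) {
    return(tibble::tibble(median_mass = numeric(), median_rt = numeric()))
  }
  long <- features_to_long_table(cl)
  # complete the grid so undetected bins are explicit missing values
  grid <- tidyr::expand_grid(
    design_mice(design)[c("mouse_id", "group")],
    region = design$regions,
    analyte_id = unique(long$analyte_id),
    bin_index = seq_len(design$n_bins) - 1L
  )
  long <- dplyr::left_join(grid, long,
                           by = c("mouse_id", "group", "region", "analyte_id", "bin_index"))
  pp <- preprocess_cohort(long, wake, design, min_mice = min_mice)
  if (nrow(pp$zmatrix) == 0) {
    return(tibble::tibble(median_mass = numeric(), median_rt = numeric()))
  }
  verdicts <- analyte_state_tests(pp$zmatrix, design, alpha = alpha)
  out <- dplyr::left_join(verdicts,
                          dplyr::rename(cl$clusters, analyte_id = "cluster_id"),
                          by = "analyte_id")
  dplyr::relocate(out, "median_mass", "median_rt")
}
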