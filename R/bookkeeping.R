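#' Bookkeeping arithmetic for a microdialysis study design
#'
#' Computes, from the per-group sample counts and preprocessing tallies that
#' a study reports, the derived totals and rates the pipeline audits: the
#' total dialysate sample count and its reconciliation against the nominal
#' design (mice x regions x bins minus missing samples), the total number of
#' imputed hourly cells (whole-series imputations times hours per series,
#' plus point imputations, plus removed outliers), the imputed fraction of
#' the coarse-grained data set, the share of imputations contributed by a
#' named subset of mice, and the outlier rate among raw observations.
#'
#' Defaults are the counts of the three-arm study this package models:
#' per-arm samples 281/278 (S6-EW3, mPFC/M1), 246/246 (EW6-S3) and 244/246
#' (SW6-EW3); 19 mice, 2 regions, 41 bins, 17 missing samples; 199 fully
#' missing series, 156 point gaps and 13 outliers over 9 hourly points of
#' 36 mPFC + 33 M1 analytes; 1299 imputations from three mice; 13 outliers
#' among 34302 raw observations.
#'
#' @param per_group_samples Integer vector of collected sample counts per
#'   (arm, region).
#' @param n_mice,n_regions,n_bins Nominal design dimensions.
#' @param n_missing_samples Samples never collected.
#' @param n_series_imputed Whole (mouse, region, analyte) series imputed.
#' @param n_hours Hourly points per series after coarse-graining.
#' @param n_point_imputed Individual missing hourly observations imputed.
#' @param n_outliers Observations removed by the outlier rule.
#' @param n_analytes_per_region Retained analyte counts per region.
#' @param subset_imputed Imputed cells contributed by the flagged mouse
#'   subset.
#' @param n_raw_observations Raw 15-min observations screened by the outlier
#'   rule.
#' @return Named list: `total_samples`, `nominal_samples`,
#'   `samples_reconciled` (logical), `imputed_cells`, `coarse_cells`,
#'   `imputed_fraction`, `subset_share`, `outlier_rate`.
#' @export
study_bookkeeping <- function(per_group_samples = c(281L, 278L, 246L, 246L, 244L, 246L),
                              n_mice = 19L, n_regions = 2L, n_bins = 41L,
                              n_missing_samples = 17L,
                              n_series_imputed = 199L, n_hours = 9L,
                              n_point_imputed = 156L, n_outliers = 13L,
                              n_analytes_per_region = c(mPFC = 36L, M1 = 33L),
                              subset_imputed = 1299L,
                              n_raw_observations = 34302L) {
  total_samples <- sum(per_group_samples)
  nominal_samples <- n_mice * n_regions * n_bins - n_missing_samples
  imputed_cells <- n_series_imputed * n_hours + n_point_imputed + n_outliers
  coarse_cells <- n_mice * sum(n_analytes_per_region) * n_hours
  list(
    total_samples = total_samples,
    nominal_samples = nominal_samples,
    samples_reconciled = total_samples == nominal_samples,
    imputed_cells = imputed_cells,
    coarse_cells = coarse_cells,
    imputed_fraction = imputed_cells / coarse_cells,
    subset_share = subset_imputed / imputed_cells,
    outlier_rate = n_outliers / n_raw_observations
  )
}
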