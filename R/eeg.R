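#' Correlate metabolite levels with EEG band power
#'
#' For each analyte and brain region, computes the Pearson correlation (and
#' two-sided p-value) between log-transformed hourly metabolite levels and
#' hourly band power, pooled over (mouse, hour) pairs within the window in
#' which the band is physiologically meaningful: 2-6 Hz activity during the
#' enforced-wakefulness hours 1-6 of the wake-first arm, slow-wave activity
#' during its recovery-sleep hours 7-9, and gamma during wake hours 1-6.
#' The log transform operates on min-shifted z values (`z - min + 1`, shift
#' per analyte-region family) since z-scores can be negative.
#'
#' @param zm Imputed z-matrix tibble.
#' @param bands Band-power table (`mouse_id`, `hour`, `band`, `power`).
#' @param design A [study_design()].
#' @param band One of `"low_2_6"`, `"swa_0p5_4"`, `"gamma_40_100"`.
#' @param window Integer hours to pool; defaults to the band's window above.
#' @param group Arm supplying the window (default `EW6_S3`, the arm with
#'   both a sustained enforced-wake period and recovery sleep).
#' @return Tibble of correlation records: `analyte_id`, `region`, `band`,
#'   `n` (pairs), `r`, `p`. Records with fewer than 3 pairs or zero variance
#'   carry `NA` and are excluded from multiple-testing families.
#' @export
correlate_band <- function(zm, bands, design,
                           band = c("low_2_6", "swa_0p5_4", "gamma_40_100"),
                           window = NULL, group = "EW6_S3") {
  band <- match.arg(band)
  if (is.null(window)) {
    window <- if (band == "swa_0p5_4") 7:9 else 1:6
  }
  bp <- bands[bands$band == band & bands$hour %in% window, ]
  x <- dplyr::filter(zm, .data$group == !!group, .data$hour %in% window)
  x <- dplyr::inner_join(x, bp[c("mouse_id", "hour", "power")],
                         by = c("mouse_id", "hour"))
  empty <- tibble::tibble(analyte_id = character(), region = character(),
                          band = character(), n = integer(),
                          r = numeric(), p = numeric())
  if (nrow(x) == 0) return(empty)
  fams <- split(x, x[c("region", "analyte_id")], drop = TRUE)
  purrr::map_dfr(fams, function(d) {
    rec <- tibble::tibble(analyte_id = d$analyte_id[1], region = d$region[1],
                          band = band, n = nrow(d), r = NA_real_, p = NA_real_)
    v <- log(d$z - min(d$z) + 1)
    if (nrow(d) < 3 || stats::sd(v) == 0 || stats::sd(d$power) == 0) return(rec)
    ct <- stats::cor.test(v, d$power, method = "pearson", alternative = "two.sided")
    rec$r <- unname(ct$estimate)
    rec$p <- ct$p.value
    rec
  })
}

#' Benjamini-Hochberg step-up correction of a correlation family
#'
#' Flags which records of one family (conventionally: one band across all
#' analytes and both regions) survive false-discovery-rate control at level
#' `q`. Records with undefined correlations are excluded from the family and
#' keep `NA`.
#'
#' @param records Correlation records from [correlate_band()].
#' @param q FDR level (default 0.05).
#' @return `records` with a logical `q_pass` column added.
#' @export
bh_correct <- function(records, q = 0.05) {
  records$q_pass <- NA
  ok <- !is.na(records$p)
  if (any(ok)) {
    records$q_pass[ok] <- stats::p.adjust(records$p[ok], method = "BH") <= q
  }
  records
}

#' Negative-control correlation analysis on the gamma band
#'
#' Runs the identical correlation and FDR machinery on gamma (40-100 Hz)
#' power during wakefulness. In data with no metabolite-gamma coupling the
#' expected number of surviving records is about `q` times the family size,
#' so this serves as a built-in specificity check of the correlation stage.
#'
#' @inheritParams correlate_band
#' @param q FDR level (default 0.05).
#' @return Correlation records with `q_pass`, as [bh_correct()].
#' @export
gamma_null_check <- function(zm, bands, design, q = 0.05, group = "EW6_S3") {
  if (!any(bands$band == "gamma_40_100")) {
    return(bh_correct(correlate_band(zm, bands[0, ], design, "gamma_40_100",
                                     group = group), q))
  }
  bh_correct(correlate_band(zm, bands, design, "gamma_40_100", group = group), q)
}
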