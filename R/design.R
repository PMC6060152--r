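#' Study design for a three-arm sleep/wake microdialysis experiment
#'
#' Describes the sampling layout shared by all pipeline stages: each mouse
#' contributes `n_bins` consecutive 15-min dialysate samples, the first
#' `n_reference` of which are collected on a slowly moving treadmill and serve
#' as the baseline reference window. The remaining bins cover 9 experimental
#' hours (`coarse_factor` bins per hour). Three experimental arms are modeled:
#'
#' * `S6_EW3` - 6 h of spontaneous sleep followed by 3 h of enforced
#'   wakefulness on the treadmill (light phase);
#' * `EW6_S3` - 6 h of wakefulness enforced with novel objects followed by
#'   3 h of recovery sleep (light phase);
#' * `SW6_EW3` - 6 h of spontaneous wakefulness followed by 3 h on the
#'   treadmill (dark phase).
#'
#' The `condition6` label of each arm (`S6`, `EW6`, `SW6`) names the
#' behavioral state that dominates the first six experimental hours and is the
#' class label used by the classification stage.
#'
#' @param n_mice_per_group Integer vector of arm sizes, named or in the order
#'   `S6_EW3`, `EW6_S3`, `SW6_EW3`. Defaults to 7, 6, 6.
#' @param n_bins Total 15-min bins collected per mouse (default 41).
#' @param n_reference Leading bins forming the baseline window (default 5:
#'   the last bin of the first treadmill hour plus the whole second hour).
#' @param coarse_factor Number of 15-min bins averaged into one hour (4).
#' @param regions Brain region labels (default `mPFC`, `M1`).
#'
#' @return An object of class `study_design`.
#' @export
study_design <- function(n_mice_per_group = c(S6_EW3 = 7L, EW6_S3 = 6L, SW6_EW3 = 6L),
                         n_bins = 41L,
                         n_reference = 5L,
                         coarse_factor = 4L,
                         regions = c("mPFC", "M1")) {
  group_names <- c("S6_EW3", "EW6_S3", "SW6_EW3")
  if (!is.null(names(n_mice_per_group))) {
    stopifnot(setequal(names(n_mice_per_group), group_names))
    n_mice_per_group <- n_mice_per_group[group_names]
  } else {
    stopifnot(length(n_mice_per_group) == 3L)
    names(n_mice_per_group) <- group_names
  }
  n_exp <- n_bins - n_reference
  if (n_exp <= 0L || n_exp %% coarse_factor != 0L) {
    stop("experimental bins (n_bins - n_reference) must be a positive multiple of coarse_factor")
  }
  n_hours <- n_exp %/% coarse_factor
  # per-hour behavioral schedule of each arm; "wake_*" states count as wake
  schedule <- list(
    S6_EW3  = c(rep("sleep", 6), rep("wake_treadmill", 3)),
    EW6_S3  = c(rep("wake_novel", 6), rep("sleep", 3)),
    SW6_EW3 = c(rep("wake_spont", 6), rep("wake_treadmill", 3))
  )
  schedule <- lapply(schedule, function(s) {
    if (length(s) >= n_hours) s[seq_len(n_hours)] else rep(s, length.out = n_hours)
  })
  design <- list(
    groups = tibble::tibble(
      group = group_names,
      n_mice = as.integer(n_mice_per_group),
      condition6 = c("S6", "EW6", "SW6"),
      schedule = unname(schedule[group_names])
    ),
    n_bins = as.integer(n_bins),
    n_reference = as.integer(n_reference),
    coarse_factor = as.integer(coarse_factor),
    n_hours = as.integer(n_hours),
    bin_minutes = 15L,
    regions = regions
  )
  class(design) <- "study_design"
  design
}

#' @export
print.study_design <- function(x, ...) {
  cat("Study design:", sum(x$groups$n_mice), "mice in", nrow(x$groups), "arms;",
      x$n_bins, "x", x$bin_minutes, "min bins per mouse (", x$n_reference,
      "reference +", x$n_hours, "h x", x$coarse_factor, "bins );",
      "regions:", paste(x$regions, collapse = ", "), "\n")
  invisible(x)
}

#' Reference-bin indices of a design (0-based)
#' @param design A `study_design`.
#' @return Integer vector of bin indices forming the baseline window.
#' @export
reference_bins <- function(design) {
  seq_len(design$n_reference) - 1L
}

#' Map 0-based bin indices to experimental hours
#'
#' Reference bins map to `NA`; the first post-reference block of
#' `coarse_factor` bins is hour 1, and so on.
#'
#' @param design A `study_design`.
#' @param bin_index Integer vector of 0-based bin indices.
#' @return Integer vector of hours in `1..n_hours` (or `NA` for reference bins).
#' @export
hour_of_bin <- function(design, bin_index) {
  out <- (bin_index - design$n_reference) %/% design$coarse_factor + 1L
  out[bin_index < design$n_reference] <- NA_integer_
  if (any(bin_index < 0L | bin_index >= design$n_bins)) {
    stop("bin_index out of range 0..", design$n_bins - 1L)
  }
  as.integer(out)
}

#' Scheduled behavioral state per (group, bin)
#'
#' @param design A `study_design`.
#' @return Tibble with `group`, `bin_index`, `hour` (`NA` in the reference
#'   window), `sched_state` (`"wake"` / `"sleep"`; the reference treadmill
#'   window is wake) and `sched_detail` (treadmill/novel/spontaneous/sleep).
#' @export
scheduled_states <- function(design) {
  bins <- tibble::tibble(
    bin_index = seq_len(design$n_bins) - 1L,
    hour = hour_of_bin(design, seq_len(design$n_bins) - 1L)
  )
  purrr::map_dfr(seq_len(nrow(design$groups)), function(g) {
    sched <- design$groups$schedule[[g]]
    detail <- ifelse(is.na(bins$hour), "wake_treadmill", sched[bins$hour])
    tibble::tibble(
      group = design$groups$group[g],
      bin_index = bins$bin_index,
      hour = bins$hour,
      sched_detail = detail,
      sched_state = ifelse(detail == "sleep", "sleep", "wake")
    )
  })
}

#' Mouse roster implied by a design
#'
#' Deterministic mouse identifiers of the form `m01`, `m02`, ... assigned to
#' arms in design order.
#'
#' @param design A `study_design`.
#' @return Tibble with `mouse_id`, `group`, `condition6`.
#' @export
design_mice <- function(design) {
  n <- design$groups$n_mice
  tibble::tibble(
    mouse_id = sprintf("m%02d", seq_len(sum(n))),
    group = rep(design$groups$group, n),
    condition6 = rep(design$groups$condition6, n)
  )
}
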