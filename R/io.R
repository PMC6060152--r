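#' @importFrom rlang .data
NULL

eeg_bands <- c("low_2_6", "swa_0p5_4", "gamma_40_100")

stop_schema <- function(...) stop("schema error: ", ..., call. = FALSE)
stop_integrity <- function(...) stop("integrity error: ", ..., call. = FALSE)

check_no_duplicates <- function(x, keys, what) {
  dup <- duplicated(x[keys])
  if (any(dup)) {
    ex <- x[which(dup)[1], keys, drop = FALSE]
    stop_integrity("duplicated ", what, " key: ",
                   paste(sprintf("%s=%s", keys, unlist(ex)), collapse = ", "))
  }
  invisible(x)
}

#' Validate a long-format sample intensity table
#'
#' Checks column presence and types, key uniqueness over
#' (mouse, region, analyte, bin), label membership against the design, bin
#' range, non-negative intensities, and that every mouse maps to exactly one
#' group.
#'
#' @param x A data frame with columns `mouse_id`, `group`, `region`,
#'   `analyte_id`, `bin_index`, `intensity` (`NA` = missing observation).
#' @param design A [study_design()].
#' @return `x` as a tibble, invisibly usable downstream.
#' @export
validate_long_table <- function(x, design) {
  cols <- c("mouse_id", "group", "region", "analyte_id", "bin_index", "intensity")
  missing_cols <- setdiff(cols, names(x))
  if (length(missing_cols) > 0) {
    stop_schema("missing columns: ", paste(missing_cols, collapse = ", "))
  }
  x <- tibble::as_tibble(x)[cols]
  bad_group <- setdiff(unique(x$group), design$groups$group)
  if (length(bad_group) > 0) stop_schema("unknown group label(s): ", paste(bad_group, collapse = ", "))
  bad_region <- setdiff(unique(x$region), design$regions)
  if (length(bad_region) > 0) stop_schema("unknown region label(s): ", paste(bad_region, collapse = ", "))
  if (any(x$bin_index < 0 | x$bin_index >= design$n_bins)) {
    stop_schema("bin_index outside 0..", design$n_bins - 1L)
  }
  if (any(!is.na(x$intensity) & x$intensity < 0)) stop_schema("negative intensity")
  check_no_duplicates(x, c("mouse_id", "region", "analyte_id", "bin_index"), "sample")
  m2g <- unique(x[c("mouse_id", "group")])
  if (anyDuplicated(m2g$mouse_id)) stop_integrity("a mouse is assigned to more than one group")
  x
}

#' Validate a wake-fraction table
#' @param x Data frame with `mouse_id`, `bin_index`, `wake_fraction`.
#' @param design A [study_design()].
#' @return `x` as a tibble.
#' @export
validate_wake_table <- function(x, design) {
  cols <- c("mouse_id", "bin_index", "wake_fraction")
  if (!all(cols %in% names(x))) stop_schema("wake table needs columns ", paste(cols, collapse = ", "))
  x <- tibble::as_tibble(x)[cols]
  if (any(is.na(x$wake_fraction)) || any(x$wake_fraction < 0 | x$wake_fraction > 1)) {
    stop_schema("wake_fraction must lie in [0, 1]")
  }
  check_no_duplicates(x, c("mouse_id", "bin_index"), "wake-fraction")
  x
}

#' Validate an EEG band-power table
#' @param x Data frame with `mouse_id`, `hour`, `band`, `power`.
#' @param design A [study_design()].
#' @return `x` as a tibble.
#' @export
validate_band_table <- function(x, design) {
  cols <- c("mouse_id", "hour", "band", "power")
  if (!all(cols %in% names(x))) stop_schema("band table needs columns ", paste(cols, collapse = ", "))
  x <- tibble::as_tibble(x)[cols]
  bad <- setdiff(unique(x$band), eeg_bands)
  if (length(bad) > 0) stop_schema("unknown band(s): ", paste(bad, collapse = ", "))
  if (any(is.na(x$power)) || any(x$power <= 0)) stop_schema("band power must be positive")
  check_no_duplicates(x, c("mouse_id", "hour", "band"), "band-power")
  x
}

read_tsv_quiet <- function(path, col_types) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  readr::read_tsv(path, col_types = col_types, na = "", progress = FALSE)
}

#' Read / write the long sample-intensity table
#'
#' Tables are tidy tab-separated files with a one-line header; missing
#' intensities are encoded as an empty field.
#'
#' @param path File path.
#' @param design A [study_design()] used for validation.
#' @return `read_long_table()` returns a validated tibble;
#'   `write_long_table()` returns `path` invisibly.
#' @export
read_long_table <- function(path, design) {
  x <- read_tsv_quiet(path, readr::cols(
    mouse_id = readr::col_character(), group = readr::col_character(),
    region = readr::col_character(), analyte_id = readr::col_character(),
    bin_index = readr::col_integer(), intensity = readr::col_double()
  ))
  validate_long_table(x, design)
}

#' @rdname read_long_table
#' @param x Table to write.
#' @export
write_long_table <- function(x, path) {
  readr::write_tsv(x, path, na = "", progress = FALSE)
  invisible(path)
}

#' Read / write the hypnogram-derived wake-fraction table
#' @inheritParams read_long_table
#' @export
read_wake_table <- function(path, design) {
  x <- read_tsv_quiet(path, readr::cols(
    mouse_id = readr::col_character(), bin_index = readr::col_integer(),
    wake_fraction = readr::col_double()
  ))
  validate_wake_table(x, design)
}

#' @rdname read_wake_table
#' @param x Table to write.
#' @export
write_wake_table <- function(x, path) {
  readr::write_tsv(x, path, na = "", progress = FALSE)
  invisible(path)
}

#' Read / write the hourly EEG band-power table
#' @inheritParams read_long_table
#' @export
read_band_table <- function(path, design) {
  x <- read_tsv_quiet(path, readr::cols(
    mouse_id = readr::col_character(), hour = readr::col_integer(),
    band = readr::col_character(), power = readr::col_double()
  ))
  validate_band_table(x, design)
}

#' @rdname read_band_table
#' @param x Table to write.
#' @export
write_band_table <- function(x, path) {
  readr::write_tsv(x, path, na = "", progress = FALSE)
  invisible(path)
}

#' Read / write the unknown spectral-feature table
#'
#' Columns: `mass` (Daltons, negative-mode parent mass), `rt` (minutes),
#' `mouse_id`, `group`, `region`, `bin_index`, `intensity`.
#'
#' @inheritParams read_long_table
#' @export
read_feature_table <- function(path, design) {
  x <- read_tsv_quiet(path, readr::cols(
    mass = readr::col_double(), rt = readr::col_double(),
    mouse_id = readr::col_character(), group = readr::col_character(),
    region = readr::col_character(), bin_index = readr::col_integer(),
    intensity = readr::col_double()
  ))
  if (any(x$mass <= 0) || any(x$rt < 0)) stop_schema("mass must be > 0 and rt >= 0")
  tibble::as_tibble(x)
}

#' @rdname read_feature_table
#' @param x Table to write.
#' @export
write_feature_table <- function(x, path) {
  readr::write_tsv(x, path, na = "", progress = FALSE)
  invisible(path)
}

#' Default run configuration
#'
#' Stage parameters for [run_pipeline()], matching the package-wide defaults:
#' outlier factor 5, detection threshold 3 mice, wrong-state threshold 0.5,
#' coarse-graining factor 4, two nearest neighbors for point imputation,
#' feature-cluster tolerances 0.0014 Da / 0.3 min, alpha 0.05, logistic
#' regularization C = 0.001, 3-fold CV with 100 repetitions, 1000 label
#' permutations, FDR level 0.05.
#'
#' @param inputs Named list of file paths (`samples`, `wake`, optional
#'   `bands`, optional `features`).
#' @param seed Integer seed governing all stochastic stages.
#' @param design Optional named list overriding the default study layout
#'   (`n_mice_per_group`, `regions`), e.g. for reduced demonstration
#'   cohorts.
#' @return A named list of configuration values.
#' @export
default_config <- function(inputs = list(), seed = 1L, design = NULL) {
  list(
    inputs = inputs,
    design = design,
    seed = as.integer(seed),
    outlier_factor = 5,
    min_mice = 3L,
    wrong_state_threshold = 0.5,
    coarse_factor = 4L,
    knn_k = 2L,
    mass_tol = 0.0014,
    rt_tol = 0.3,
    alpha = 0.05,
    C = 0.001,
    cv_folds = 3L,
    cv_reps = 100L,
    perm_cv_reps = 3L,
    n_permutations = 1000L,
    fdr_q = 0.05
  )
}

#' Read a YAML run configuration
#'
#' Unspecified keys fall back to [default_config()] values.
#'
#' @param path Path to a YAML file.
#' @return A configuration list.
#' @export
read_run_config <- function(path) {
  user <- yaml::read_yaml(path)
  cfg <- default_config()
  cfg[names(user)] <- user
  cfg$seed <- as.integer(cfg$seed)
  cfg
}
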