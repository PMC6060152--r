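# Scaled-down generator settings used across tests: fewer analytes and a
# smaller unknown-feature panel keep the mixed-model machinery fast while
# preserving the 7/6/6 three-arm layout and every artifact type.
small_params <- function(seed = 1L, ...) {
  args <- list(
    seed = seed,
    n_known_analytes = 12L, n_state_dependent = 4L, n_depletion = 2L,
    n_unknown_features = 4L, n_unknown_state_dependent = 1L,
    n_planted_outliers = 5L
  )
  user <- list(...)
  args[names(user)] <- user
  do.call(generator_params, args)
}

small_cohort <- function(seed = 1L, ...) {
  simulate_cohort(small_params(seed = seed, ...))
}

# deterministic 2-mouse toy long table: m1/m2 in different arms, one region
# per call unless both requested
toy_long_table <- function(n_analytes = 3, regions = c("mPFC", "M1"),
                           design = study_design()) {
  grid <- tidyr::expand_grid(
    mouse_id = c("m1", "m2"),
    region = regions,
    analyte_id = sprintf("a%02d", seq_len(n_analytes)),
    bin_index = seq_len(design$n_bins) - 1L
  )
  grid$group <- ifelse(grid$mouse_id == "m1", "S6_EW3", "EW6_S3")
  grid$intensity <- 1000 + seq_len(nrow(grid)) %% 97
  grid[c("mouse_id", "group", "region", "analyte_id", "bin_index", "intensity")]
}

# central-difference gradient for stationarity checks
numDeriv_grad <- function(f, x, h = 1e-5) {
  vapply(seq_along(x), function(i) {
    e <- numeric(length(x)); e[i] <- h
    (f(x + e) - f(x - e)) / (2 * h)
  }, numeric(1))
}
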