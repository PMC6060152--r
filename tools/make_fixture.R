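# Regenerates the packaged demonstration cohort under inst/extdata/.
# The fixture is a deliberately reduced synthetic cohort (3 mice per arm,
# one brain region, 4 known analytes, 2 unknown feature clusters) so the
# full pipeline runs in seconds and the files stay small. Run from the
# package root:  Rscript tools/make_fixture.R
devtools::load_all(".", quiet = TRUE)

params <- generator_params(
  seed = 20180725L,
  n_mice_per_group = c(S6_EW3 = 3L, EW6_S3 = 3L, SW6_EW3 = 3L),
  n_known_analytes = 4L, n_state_dependent = 2L, n_depletion = 1L,
  n_unknown_features = 2L, n_unknown_state_dependent = 1L,
  p_series_missing = 0, p_point_missing = 0.01, p_hour_missing = 0.01,
  n_planted_outliers = 2L
)
design <- study_design(params$n_mice_per_group, regions = "mPFC")

# the generator builds both regions from the default design; regenerate at
# the reduced design by overriding the region list through simulate_cohort
sim <- local({
  p <- params
  sim_full <- simulate_cohort(p)
  keep <- sim_full$samples$region == "mPFC"
  list(samples = sim_full$samples[keep, ],
       wake = sim_full$wake,
       bands = sim_full$bands,
       features = sim_full$features[sim_full$features$region == "mPFC", ])
})

dir.create("inst/extdata", recursive = TRUE, showWarnings = FALSE)
sim$samples$intensity <- round(sim$samples$intensity)
write_long_table(sim$samples, "inst/extdata/demo_samples.tsv")
sim$wake$wake_fraction <- round(sim$wake$wake_fraction, 4)
write_wake_table(sim$wake, "inst/extdata/demo_wake.tsv")
sim$bands$power <- round(sim$bands$power, 2)
write_band_table(sim$bands, "inst/extdata/demo_bands.tsv")
feats <- sim$features[c("mass", "rt", "mouse_id", "group", "region",
                        "bin_index", "intensity")]
feats$mass <- round(feats$mass, 5)
feats$rt <- round(feats$rt, 3)
feats$intensity <- round(feats$intensity)
write_feature_table(feats, "inst/extdata/demo_features.tsv")

writeLines(c(
  "# Demonstration run configuration for the packaged synthetic cohort.",
  "# Input paths are resolved against the package extdata directory; see",
  "# the README for a worked example.",
  "seed: 1",
  "design:",
  "  n_mice_per_group: {S6_EW3: 3, EW6_S3: 3, SW6_EW3: 3}",
  "  regions: [mPFC]",
  "n_permutations: 50",
  "cv_reps: 25"
), "inst/extdata/demo_config.yaml")
cat("fixture written\n")
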