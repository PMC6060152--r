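# Demonstration run configuration for the packaged synthetic cohort.
# Input paths are resolved against the package extdata directory; see
# the README for a worked example.
seed: 1
design:
  n_mice_per_group: {S6_EW3: 3, EW6_S3: 3, SW6_EW3: 3}
  regions: [mPFC]
n_permutations: 50
cv_reps: 25
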