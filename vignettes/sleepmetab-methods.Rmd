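---
title: "Models and methods behind sleepmetab"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind sleepmetab}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem this package addresses

Brain microdialysis yields timed fractions of extracellular fluid whose
untargeted mass-spectrometric profiles track the animal's physiological
state. `sleepmetab` implements a complete analysis pipeline for such data
collected across sleep, spontaneous wakefulness and enforced wakefulness in
a three-arm mouse design:

* **S6_EW3** — about 6 h of spontaneous sleep followed by 3 h of enforced
  wakefulness on a treadmill (light phase);
* **EW6_S3** — 6 h of wakefulness enforced with novel objects followed by
  3 h of recovery sleep (light phase);
* **SW6_EW3** — 6 h of spontaneous wakefulness followed by 3 h on the
  treadmill (dark phase).

Each mouse contributes 41 fifteen-minute dialysate samples per brain region
(medial prefrontal cortex and primary motor cortex): a 5-bin treadmill
reference window (end of hour 1 plus all of hour 2) and 36 experimental
bins covering 9 h. Contrasting the arms separates behavioral state from
time of day, lighting and the stimulation used to keep mice awake.

The pipeline answers, per analyte: does its extracellular level change with
behavioral state (and in which direction); how does its decline differ
between early, late and recovery sleep; can the joint metabolite profile
classify the behavioral state of a sampling epoch; and does its time course
correlate with EEG markers of sleep pressure.

# Preprocessing ladder

The ladder runs in a fixed order; each rung is an exported function and
`preprocess_cohort()` chains them.

1. **Detection filter.** An analyte is retained in a region only if it has
   at least one observation in at least `min_mice = 3` mice of *every* arm,
   assessed per region. This guards the mixed models against analytes
   detectable in only a few animals.
2. **Baseline z-scoring.** Every (mouse, region, analyte) series is
   standardized by the mean and standard deviation of its own reference
   window: `z = (x - mu_ref) / sd_ref`. Standardization is per series, so
   between-mouse abundance differences and ionization efficiency cancel.
   A series with fewer than two reference observations or zero reference
   variance cannot be standardized and is dropped with a logged reason; a
   series with no observations at all passes through as all-missing and is
   later filled by tier-1 imputation.
3. **Outlier rule.** An observation is removed when its absolute z-score
   exceeds `outlier_factor = 5` times every other absolute z-score of its
   series. Absolute values make the rule symmetric for analytes that move
   below baseline; with a factor above 1 at most one observation per series
   can fire. The rule runs on the 15-min series, before coarse-graining.
4. **Wrong-state exclusion.** A bin is discarded when the hypnogram
   contradicts the arm's schedule by strictly more than
   `wrong_state_threshold = 0.5`: scheduled sleep with more than half the
   bin awake, or scheduled wake with more than half asleep. The boundary is
   strict, so a bin at exactly 50% is retained.
5. **Coarse-graining.** Post-reference bins are averaged in blocks of 4
   into hourly values (9 per series). An hourly value is the mean of its
   non-missing members; it is missing only when all members are missing.
   Partial blocks therefore keep their data.
6. **Two-tier imputation.** Tier 1: a series with no observed hour receives
   at every hour the mean observed z of the other mice of the same arm,
   region, analyte and hour. Tier 2: remaining gaps receive the mean of the
   two nearest observed hours of the same series (nearest by hour distance,
   ties toward earlier hours; both neighbors may sit on one side at an
   edge; a single observed hour is copied). Tier-2 neighbors are restricted
   to originally observed hours, so imputations never chain. Every cell
   carries provenance (`observed`, `imputed_tier1`, `imputed_tier2`) and
   the audit reports counts per tier and the imputed fraction.

Two consequences of imputation are worth stating plainly, because they
shape decisions downstream:

* the mixed models fit on *observed* hourly cells only. Tier-1 cells are
  copies of a condition mean, so feeding them to a test of condition
  differences counts the same evidence twice; tier-2 cells interpolate
  their neighbors and understate residual variance exactly where gaps
  concentrate — wrong-state discards cluster in the wake-then-sleep arm's
  recovery window, which is precisely that model's phase-contrast window,
  and with tier-2 cells included its null rejection rate ran at 12.5%
  versus roughly 5% elsewhere. Mixed models tolerate missingness natively;
  that robustness is the standard reason to choose them for repeated
  measures, and fitting them on the observed data restores the false-
  verdict rate of the state-specificity rule to below 5% (3.7% over 300
  null analytes at default conditions, with 99% sensitivity).
* a classifier trained on a matrix containing tier-1 cells is optimistic:
  the filled-in values encode the class. The classification stage uses the
  complete matrix (its contract requires no missing entries), so observed
  accuracies on heavily series-imputed data should be read against the
  permutation distribution, not against nominal chance. The machinery's
  own calibration is checked on cohorts generated without whole-series
  dropouts.

# Unknown spectral features

Untargeted acquisition yields peaks identified only by exact parent mass
and retention time. Two observations measure the same unknown compound
when their masses differ by less than `mass_tol = 0.0014` Da and retention
times by less than `rt_tol = 0.3` min (both strict). Because this pairwise
relation is not transitive, features are partitioned by its transitive
closure — single-linkage clustering — which is order-independent and the
minimal closure of the stated rule. Cluster centroids are medians (robust
to a stray tail feature); retention-time tolerance is taken in minutes,
the scale on which such tables are conventionally printed. Clusters then
flow through the identical preprocessing and testing path as known
analytes, keyed by (median mass, median RT). When several observations of
one cluster fall in the same sample, the most intense is kept.

# Mixed-effects state analysis

For analyte response $Y_{i,t}$ of mouse $i$ at hour $t$,

$$Y_{i,t} = \beta_0 + b_{i,0} + \sum_p \beta_p X_{i,t,p}
          + \sum_q b_{i,q} Z_{i,t,q} + \epsilon_{i,t},
\qquad b_{i,q} \sim N(0, \sigma_q^2),\quad
\epsilon_{i,t} \sim N(0, \sigma^2).$$

All fits are maximum likelihood (`lme4`), because AIC comparison and
likelihood-ratio testing across different fixed structures require it.

**Three models per analyte.** The between-groups model uses hours 1–6 of
all arms (condition = S6/EW6/SW6, the state dominating those hours), both
regions pooled with region fixed effects. The two within-group models use
hours 1–9 of one arm each, with condition = behavioral phase (sleep/wake,
switching at hour 6).

**Response transform.** Identity, log or square root, chosen to minimize
the absolute skewness of pilot-fit residuals. Log and square root operate
on min-shifted values `y - min(y) + 1`, since z-scores can be negative;
the shift is recorded. Identity wins ties.

**Random effects.** Candidates are a per-mouse intercept and a per-mouse
time slope. The maximal structure is kept only while supported: slope
variance above `v_tol = 1e-6` and intercept–slope correlation below
`c_tol = 0.99` in absolute value; otherwise the slope is dropped. The
intercept is never dropped. Whenever both regions are pooled, a
per-(mouse, region) *series* intercept is always added: each series is
standardized against its own 5-sample baseline, so all of its z-values
share the baseline estimation error as a common offset (standard deviation
about $1/\sqrt{5}$ of the residual scale). Without the series term that
offset masquerades as a region-specific condition effect and the
condition-by-region test rejects wildly (null p-values near $10^{-7}$ were
observed in simulation).

**Fixed-effect selection and the condition test.** AIC selects the
*supporting structure* — the time trend and region terms — by comparing
fits of hierarchy-respecting subsets of {time, region} *without any
condition term*. The tested full model is the selected structure plus a
deterministic condition block: the condition main effect and its
interaction with each structural term present. The likelihood-ratio test
removes the whole block. Two measured facts drove this design:

* letting the criterion see condition terms (directly, or riding along
  with a structural term) selects the contrast that happens to look strong
  and then tests it — null rejection rates of 14–21% at nominal 5% in
  simulation;
* in the within-group models the phase contrast is itself a function of
  time (phase = late hours), so structure selection that may drop the time
  trend suppresses the aliased contrast and makes the test conservative
  (2.7% observed). Time therefore stays in every within-model candidate.

**Reference distribution.** For the within-group models condition varies
within mice and the usual $\chi^2_q$ reference is calibrated (4-6% at
nominal 5% across repeated 600-800-replicate null simulations of the two
arms). For the between-groups model condition is constant per mouse; with 19 mice the
$\chi^2$ reference ignores the uncertainty of the estimated between-mouse
variance and rejected 14% of nulls. The statistic is therefore rescaled to
`stat / q` and referred to $F(q,\ \mathrm{ddf})$ with a containment-style
denominator `ddf = n_mice - 1 - (K - 1) = 16` counting the between-mouse
parameters — measured null rejection 4.2%. (This is a fixed counting rule,
not an estimated-degrees-of-freedom method.) Pooled over the three models
the machinery rejects at about 5% under the null.

**Direction and the state-specificity verdict.** The direction of each
model (wake-higher vs sleep-higher) is the sign of the model-implied
wake-minus-sleep contrast at the end of the modeled window (hour 6
between-groups, hour 9 within-group), averaged over regions. It is read
from the *descriptive* full-interaction model rather than the selected
one: with a rise-then-fall within-group profile, a main-effects-only fit
places the post-transition phase at the trajectory peak and misstates
which state is higher, while the direction clause is precisely a
trajectory-consistency check. An analyte is **state-specific** when at
least one model is significant at `alpha = 0.05` *and* all three
directions agree. Analytes declining in every state (depletion during
prolonged sampling) fail the direction-agreement clause by construction of
the rule, not by a special case.

**Sleep-phase typing.** Early sleep (hours 1–3, sleep-first arm), late
sleep (hours 4–6, same arm) and recovery sleep (hours 7–9, wake-first arm)
are compared per region with `y ~ sleep_condition * time + (1 | mouse)`,
time recoded 1–3 within each window. The interaction is tested by
likelihood ratio (2 df; $\chi^2$ measured calibrated at 5.3% over 1000
null replicates — the contrast is largely within-mouse). With a
significant interaction and both compared slopes negative, the analyte is
Type 1 (early and recovery decline at similar rates; slope contrast not
significant), Type 2 (recovery declines significantly faster) or Type 3
(early declines significantly faster); a non-declining compared slope
yields "other". The early-vs-recovery contrast is an uncorrected Wald
z-test on the recovery-by-time coefficient.

# Classification

**Feature matrix.** Observation units are mouse-hour epochs over hours
1–6; columns are region-tagged analytes from both regions; the label is
the arm's dominant state. Mice — not epochs — are the unit of fold
assignment, so all epochs of a mouse stay together.

**PLS-DA.** Partial least squares regression of the one-hot label matrix
on standardized features, by the classical iterative (NIPALS) algorithm
with deflation; two components are reported. Weight vectors have unit norm
and score vectors are mutually orthogonal. The variable importance in
projection of feature $j$ over $A$ components is

$$\mathrm{VIP}_j = \sqrt{p \sum_a \mathrm{SSY}_a\,
  (w_{ja}/\lVert w_a\rVert)^2 \Big/ \sum_a \mathrm{SSY}_a},$$

with $p$ the feature count and $\mathrm{SSY}_a$ the Y-variance captured by
component $a$; the mean of squared VIPs is exactly 1, making VIP > 1 the
conventional importance threshold.

**Penalized logistic classifier.** Multinomial (softmax) logistic
regression minimizing
$\sum_i -\log p(y_i \mid x_i) + \lVert W \rVert^2 / (2C)$ with
`C = 0.001`, solved by BFGS on the convex objective with analytic
gradient. The penalty applies to the full parameter matrix including
intercepts: that keeps the symmetric softmax parameterization identifiable
and gives the fully-shrunk limit exchangeable class predictions rather
than majority-class predictions — the behavior under which permutation
accuracy sits at 1/k for k classes even in this unbalanced (7/6/6) design.
(The parameter C is often described as a sparsity control; an $\ell_2$
penalty shrinks coefficients smoothly rather than zeroing them, and it is
implemented here exactly as stated.) Ties in predicted scores break to the
first class level, deterministically.

**Cross-validation and significance.** Repeated stratified 3-fold
cross-validation partitions mice with arm counts approximately equal per
fold; feature standardization uses training-fold statistics only; each
repetition's accuracy is the fraction of held-out epochs labeled
correctly; the non-parametric 95% confidence interval is the 2.5/97.5
percentile of the repetition accuracies (100 repetitions by default).
Significance comes from mouse-level label permutation:
`p = (1 + #{perm >= observed}) / (1 + n_permutations)`, 1000 permutations
by default, with a handful of CV repetitions inside each permutation (the
p-value integrates over permutations, so per-permutation repetitions add
little). Pairwise comparisons restrict the epochs to two arms and rerun
the full machinery (chance 50%).

# EEG band correlations

Hourly band power is consumed pre-computed. For each analyte and region,
Pearson's r (with the two-sided t-based p) is computed over pooled
(mouse, hour) pairs of log-transformed level (min-shifted, as in the
models) against band power, within the window where the band is
meaningful: 2–6 Hz activity during enforced-wake hours 1–6 of the
wake-first arm, slow-wave activity during its recovery hours 7–9, gamma
(40–100 Hz) during wake as a negative control. Pooled mouse-hours are the
correlation unit. Each band's records across analytes and both regions
form one Benjamini–Hochberg family at `fdr_q = 0.05`. Records with fewer
than 3 pairs or zero variance are excluded from the family. On data with
no planted gamma coupling the expected surviving fraction of the gamma
family is about the FDR level — a built-in specificity check.

# The synthetic cohort generator

The generator (`simulate_cohort()`) emits the four tables the pipeline
consumes plus the ground truth needed to score every stage. Its defaults
*are* the study conditions: arms of 7/6/6 mice, two regions, 41 bins with
a 5-bin reference window, 36 known analytes of which 11 are
wake-upregulated and 3 decline in every state, whole-series / whole-hour /
point missingness, planted outliers, unknown features in well-separated
(mass, RT) clusters with jitter a tenth of the clustering tolerances, and
EEG bands coupled to wake/sleep history.

Key mechanisms and the reasoning behind them:

* **State-integral drift.** Log-intensity drifts by `wake_slope = 0.3`
  baseline-noise units per awake hour and `sleep_slope = -0.3` per asleep
  hour, accumulated over the actual per-bin wake fractions — matching the
  roughly linear hour-scale trends of state-coupled dialysate metabolites,
  and making the planted effect magnitude an explicit, recoverable target.
* **Lognormal intensities with per-mouse intercepts**
  (`noise_sd = 0.25`, `mouse_re_sd = 0.3` on the log scale), so raw values
  are positive, z-scoring is nontrivial, and the transform-selection step
  has real work to do.
* **Hierarchical wake bouts.** Each (mouse, hour) draws a state tendency
  and bins concentrate around it, so occasional wrong-state *hours*
  contradict the schedule in all four bins — the realistic source of
  hour-scale gaps that exercises tier-2 imputation via the wrong-state
  filter.
* **Planted outliers** replace an observed post-reference sample with a
  value whose baseline z-score is 7 times the series' largest other
  |z|, guaranteeing the 5x rule fires on exactly the planted coordinates.
* **Band coupling.** 2–6 Hz power rises with cumulative wake (slope 8
  units/h) around hourly fluctuations of sd `band_noise_sd = 60`;
  slow-wave activity starts high and decays across recovery sleep; gamma
  is flat noise. Each state-dependent analyte's log-level is coupled to
  the 2–6 Hz fluctuation with gain `kappa_mag = 0.008` and alternating
  sign. The pair (gain, fluctuation scale) satisfies two explicit
  constraints: the coupling covariance dominates the shared time-trend
  covariance (|kappa| x sd^2 = 28.8 > 8.4), so the planted correlation
  sign — stored analytically in the ground truth — is recoverable even for
  negatively coupled analytes; and the coupling contributes only ~0.5
  z-units of hourly noise, so mixed-model power is not destroyed by the
  band fluctuation that all coupled analytes share.

What the generator does **not** emulate: batch and run-order effects,
adducts and in-source fragments beyond pre-removed isotopes, probe
recovery drift, heteroscedasticity across analytes, REM/NREM
substructure, or circadian rhythmicity beyond the schedule itself.
Passing recovery tests therefore demonstrates that the pipeline's logic is
sound under the study's design and realistic noise — not that it is robust
to every artifact of a real LC-MS campaign.

Null cohorts for calibration set both slopes to zero. Cohorts for
null-soundness of the *permutation machinery* additionally set
`p_series_missing = 0`, isolating the machinery from the label information
that condition-mean imputation injects (see the preprocessing section);
with that isolation the permutation p-values are uniform (Kolmogorov-
Smirnov p = 0.91 over 20 replicate cohorts).

# Numerical choices and degenerate inputs

* lme4 fits use `nloptwrap` with derivative checks off for speed; a
  negative likelihood-ratio statistic beyond 1e-6 triggers a refit with
  `bobyqa`, and small negatives clamp to zero.
* The logistic objective uses the max-shifted softmax for overflow safety;
  BFGS stops at a relative tolerance of 1e-10.
* NIPALS stops when the score vector changes by less than 1e-10
  relatively, with a 500-iteration cap.
* Single-linkage clustering sorts by mass and unions only within a sliding
  mass window, avoiding the full pairwise matrix.
* Degenerate inputs fail loudly and early: duplicate keys, unknown
  labels, negative intensities, wake fractions outside [0,1] and
  non-positive band powers are schema/integrity errors; a cell imputable
  by neither tier aborts with its coordinates; a zero-variance feature
  column is an error naming the column; single-observation series warn and
  flag nothing.

# Problem sizes used by the test suite

The suite validates the full-size design (7/6/6 mice, both regions) for
calibration and recovery, with scaled simulation counts chosen to keep the
suite responsive: 160 null replicates per state model (480 pooled) and 500
for the sleep-phase test; 8 generator seeds for verdict recovery on
full-size 36-analyte cohorts; 60–200 label permutations for chance
calibration; 5-seed property loops elsewhere, usually on reduced
12-analyte cohorts. Development-time measurements quoted above (600–1000
replicates, 12-seed full-cohort sweeps) used the same generators at larger
counts.

# Known limitations

* The between-groups F reference uses a fixed containment denominator; it
  is calibrated at this design's size but is not a general small-sample
  theory.
* Verdict-level error control is inherited from three correlated tests
  plus a direction gate; it is validated empirically (3.7% false verdicts
  and 99% sensitivity at default effect sizes over 12 generator seeds),
  not analytically. The three model directions are positively correlated
  for null analytes (they share mice), so the direction-agreement gate
  screens out fewer chance significances than independence would suggest.
* Observed (non-permutation) classification accuracy on heavily
  series-imputed data is optimistic, as discussed; the permutation p-value
  is the honest significance summary.
* Real-data tables of the motivating study are not redistributable, so
  numerical agreement with its printed per-analyte statistics is out of
  scope; the package validates against its own synthetic ground truth and
  the study's printed bookkeeping arithmetic.
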