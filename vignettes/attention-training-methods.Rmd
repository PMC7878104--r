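---
title: "Methods: individualized dot-probe attention training pipelines"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: individualized dot-probe attention training pipelines}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dotprobe)
```

# Overview

`dotprobe` implements the computational core of an individualized
attention-bias-modification intervention: (1) turning a participant's own
treatment-related thoughts and their pairwise similarity ratings into a
2D cognitive map and a probe-target/distractor partition; (2) planning
and executing modified dot-probe training sessions whose probe placement
is contingent on stimulus class; (3) reducing raw trial logs to
attentional-processing-speed summaries; (4) scoring the outcome
instruments and computing pre/post statistics and effect sizes; and (5)
generating synthetic cohorts so that every stage is testable without
participant data.

This vignette records the model choices, defaults, and numerical
decisions, and what the simulation results do and do not establish.

# Stimulus assessment

## Similarity ratings and their reversal

Participants rate the similarity of every unordered pair of their
elicited thoughts (presented in seeded random order by
`pair_schedule()`). Ratings live on a bounded scale `[s_min, s_max]`
(default 1–9; the bounds are a parameter because elicitation protocols
vary). `to_dissimilarity()` applies the linear reversal
`d_ij = s_max − s_ij`: the simplest monotone transform, and since the
embedding downstream is *nonmetric*, any strictly monotone reversal
yields the same solution — only the rank order of the dissimilarities
matters.

## Nonmetric MDS by stress majorization

`mds_embed()` fits a 2D configuration by SMACOF (stress majorization)
with monotone disparities:

* **Loss.** Kruskal stress-1,
  `sqrt(sum((dhat − d)^2) / sum(d^2))`, where `d` are configuration
  distances and `dhat` the isotonic (monotone least-squares) fit of `d`
  onto the dissimilarity order. Similarity ratings of personal thoughts
  are ordinal at best, so a nonmetric fit is the defensible choice.
* **Ties.** Ties among dissimilarities are broken in favor of the
  current configuration distances (the "primary" approach: tied
  dissimilarities may be untied), which can only reduce stress and makes
  the isotonic step deterministic.
* **Update.** The Guttman transform with unit weights. Coincident points
  (zero configuration distance) contribute zero to the transform, the
  standard guard.
* **Monotonicity.** Majorization makes stress non-increasing; a
  safeguard additionally terminates iteration if a numerical uptick
  larger than 1e-12 ever appears, so the reported per-iteration stress
  trace is non-increasing by construction.
* **Initialization and restarts.** The first start is the classical
  (Torgerson double-centering) solution; `n_init − 1` further random
  starts (seed-governed) protect against local minima. The *earliest*
  start within 1e-8 of the minimum stress is returned, so when a random
  restart merely ties the classical solution (always the case at very
  small n, where a nonmetric fit is weakly constrained) the
  metrically-informed configuration is preferred. This is why exact
  planar inputs are recovered to machine precision rather than only up
  to a monotone distortion.
* **Convergence.** Stop when the relative stress decrease falls below
  `tol` (default 1e-6) or after `max_iter` (default 300) iterations.
* **Degenerate input.** An all-zero dissimilarity matrix returns all
  points at the origin with stress 0 and no iterations.

Recovery is diagnosed with `procrustes_rmsd()`, which aligns
configurations by translation, rotation/reflection and (by default)
uniform scaling — the transforms an MDS solution is not identified
against.

## Classification into probe targets

`classify_for_training()` partitions stimuli by their elicited labels:
probe targets are stimuli with orientation in {approach, neutral} *and*
valence in {positive, neutral}; everything else is a distractor. The
cognitive map is attached as diagnostic provenance only. The design
alternative — deriving the partition from map coordinates — would require
a coordinate-to-category rule that the elicitation protocol does not
define; inventing a threshold in an unidentified coordinate system would
manufacture structure, so the labels govern.

# Session engine

Protocol constants (all configurable via `protocol_constants()`):
1000 ms fixation; 2500 ms stimulus exposure (fixed, though deployed
timing is only approximate); 50 trials x 4 blocks per session; 3
sessions/day x 28 days = 84 target sessions; tutorial gate at 80%
accuracy, read as *inclusive* (accuracy exactly 0.80 passes); response
timeout 5000 ms after probe onset (recorded as `response_side = "none"`,
counted incorrect); inter-trial interval 0 ms.

Planning decisions in `build_session_plan()`:

* **Pairing-type allocation.** 50 is not divisible by the 4 pairing
  types, so each block allocates 13/13/12/12, with the two types
  receiving 13 rotated across blocks (offset seeded), making a complete
  session exactly 50 trials per type.
* **Probe placement.** The probe-side member of *every* trial is drawn
  from the probe-target partition with the valence the pairing type
  requires: the positive member for positive-neutral and
  positive-negative pairs, the neutral member for negative-neutral
  pairs, and a neutral-valence probe target for neutral-neutral pairs.
  The probe therefore never lands on a negative or avoidance-oriented
  stimulus, including on neutral-neutral trials.
* **Side counterbalancing.** Within each block the probe-target's
  left/right position is counterbalanced to 25/25 (odd per-type counts
  alternate which side gets the extra trial), then trial order is
  shuffled. This satisfies both the ~50/50 requirement and, through the
  shuffle, makes the side unpredictable trial-to-trial; we chose exact
  counterbalancing over independent uniform draws for neutral-neutral
  trials because it dominates it on balance without affecting
  unpredictability.
* **Feedback.** Error-only: the deployed app's audible alert is modeled
  as a boolean `feedback_emitted` on incorrect trials. Whether feedback
  also accompanied correct responses is ambiguous in descriptions of
  such protocols; error-only is the conservative reading.

Session completeness is all-or-nothing at block granularity: a
`session_log` is complete only with all 200 trials, and
`protocol_adherence()` counts only complete sessions.

Logs serialize to JSON lines (header record + one record per trial),
chosen because trial streams are append-safe mid-session; the
round-trip is bit-exact (full-precision numerics) and malformed lines
are rejected with line numbers.

# Reaction-time pipeline

* `filter_correct()` keeps correct responses only — incorrect responses
  and timeouts never enter RT summaries.
* `trim_outliers()` removes RTs more than k = 1.5 SD above or below the
  participant's mean. The reference distribution is the participant's
  correct RTs within one assessment period, pooled across pairing types,
  and the rule is applied in a single pass (no re-trimming): this is the
  most literal reading of "a participant's mean response time" and the
  simplest reproducible rule. Zero-variance groups are kept whole;
  groups with fewer than 2 observations pass through with a warning.
  Under a normal law the retained fraction converges to
  `2*pnorm(1.5) − 1 ≈ 0.866`; for the right-skewed ex-Gaussian the trim
  is asymmetric in effect, which is exactly why it matters.
* `pairing_means()` computes participant-level means per pairing type
  and period first, then cohort means and SDs *over participants*, so
  each participant contributes equally and the reported SD is
  between-person dispersion (~700 ms at baseline in the emulated
  conditions, not the within-person trial SD). Baseline vs posttraining
  is a two-sided paired t on participant means (df = n − 1), pairwise
  excluding participants missing a period.
* `accuracy_table()` uses the *untrimmed* observations including errors
  and timeouts.

# Outcome statistics

* **Effect-size conventions.** For pre/post means,
  `cohen_d_paired(t, n) = |t|/sqrt(n)` — the standardized mean change
  (mean difference over SD of differences). It is the convention that
  reproduces the published worked examples exactly
  (`4.16/sqrt(12) = 1.20`, `2.71/sqrt(12) = 0.78`,
  `3.48/sqrt(12) = 1.00`); the signed raw-vector version is available as
  `cohen_d_change()`. For 2x2 categorical change,
  `phi_effect(chi2, n) = sqrt(chi2/n)` with n = participants
  (`sqrt(5.6/12) = 0.68`).
* **Paired categorical change.** `categorical_change_test()` builds the
  pre-by-post 2x2 participant table and computes the Pearson chi-square
  without continuity correction. A published chi-square for such a
  design cannot be re-derived from the marginal counts alone (the
  off-diagonal split is unidentified from margins), so the package
  exposes the full table; degenerate margins are flagged rather than
  computed.
* **Degenerate paired t.** Identical pre/post vectors return t = 0,
  p = 1; constant nonzero differences return a signed infinite t; both
  are flagged `degenerate` rather than erroring mid-pipeline.
* **Instrument scoring.** PHQ-9 (9 items, 0–3): bands ≤4 / 5–9 / 10–14 /
  15–19 / ≥20 and the ≥10 cutoff flag; PCL-C (17 items, 1–5): totals
  17–85, screen at ≥30; MMS anxiety subset (9 items, default
  dichotomous coding, configurable because administrations vary):
  elevated at ≥6; VAS adherence bins 1–3 (≤75%) = low, 4 = moderate/high.
  Missing items flag the score incomplete — never imputed; malformed
  item vectors (wrong length or range) are rejected.
* p-values are two-sided throughout; no multiple-testing correction is
  applied, matching the descriptive, exploratory analysis style the
  pipeline reproduces. Scores are screeners, not diagnoses.

# Synthetic cohort generator

The generator's defaults *are* the emulated study conditions; they were
fixed from the published summary structure and are not tuned thereafter.

* **RT model.** Person baseline intercepts `N(2550, 700)` ms (truncated
  below at 1000 ms); pairing-type offsets (+3, +29, +11, −67) ms giving
  baseline means 2553/2579/2561/2483; trial-level ex-Gaussian noise
  (sigma 150 ms, tau 200 ms, mean-anchored) producing realistic right
  skew — the feature that makes the 1.5 SD trim consequential.
* **Training effect.** Mean reduction 330 ms with per-pairing offsets
  (+23, −6, +39, −22) giving 353/324/369/308 ms; an idiosyncratic
  person-level SD of 80 ms; and a coupling of 0.45 to the person's
  baseline deviation (slower participants improve more). The coupling
  emulates the compression of between-person dispersion after training
  (posttraining SD ≈ sqrt((0.55·700)² + 80²) ≈ 390 ms against observed
  331–414 ms) without changing the mean reduction.
* **Errors.** Independent Bernoulli lapses (4% baseline, 2% post) plus a
  0.5% timeout rate; a lapse answers the wrong side regardless of
  attentional state. How errors actually arise in a two-location task at
  94–98% accuracy is not observable from summary data; lapses are the
  minimal mechanism.
* **Surveys.** Baseline PHQ-9 latent `N(13.4, 6.8)` truncated to 0–27;
  person-level change `N(d·sigma_c, sigma_c)` with d = 1.2 and
  sigma_c = 4 (chosen so the implied mean change, 4.8 points, and its SD
  match the published paired t at n = 12). Totals are split into 9 items
  of 0–3 by an even-floor-plus-seeded-remainder scheme; only totals are
  contractually meaningful. Adherence: low at baseline with probability
  5/12; low→moderate/high transitions with probability 0.4 (expected
  posttraining low fraction 0.25), no worsening by default. PCL-C and
  MMS totals are generated as descriptive covariates correlated with
  depressive symptoms.
* **Determinism.** Every artifact derives from `params$seed` through a
  fixed sub-seed scheme; the same parameter object reproduces the cohort
  exactly. Cohort-scale trial generation uses a vectorized simulator
  that emits logs schema-identical to `run_session()` (asserted by
  test); the responder-driven path remains the engine's contract for
  interactive/simulated responders.

**What passing simulations show — and do not.** Parameter recovery
(e.g. mean recovered PHQ-9 d within ±0.15 of the generating 1.2 over 200
cohorts of n = 12) demonstrates that the pipeline's arithmetic is
faithful to its own generative model and approximately unbiased at the
study's scale. It does not validate the generative model against real
participants: real RT distributions have sequential dependencies,
fatigue and practice trends within session, and error processes
correlated with speed, none of which the lapse/ex-Gaussian model
contains. Pooled-reference trimming also biases *per-pairing* means
slightly toward the pooled mean (visible as a few ms of bias for the
pairing types farthest from it), a property of the trimming rule itself,
not of the implementation.

# Problem sizes and runtime choices

The test suite exercises: embeddings at n = 3–12 stimuli; session plans
across 10 seeds; a 100,000-observation trimming check; and a 200-cohort
x n = 12 recovery study (the intended desk scale for this design, and
the scale at which the Monte-Carlo CI on the mean is a few ms wide for
RT reductions and ~0.06 for d). `parameter_recovery_suite()` caps
`n_reps` at 200 accordingly.

# Known limitations

* The attention-bias index of the standard (assessment) dot-probe task —
  incongruent minus congruent RT — is out of scope by design: the
  training task has no incongruent probes, so only processing-speed
  change is measurable.
* Nonmetric MDS at small n is weakly constrained; stress near zero at
  n ≤ 5 carries little information. The classical-start preference makes
  the solution reproducible, not more identified.
* The counseling component of the motivating intervention design is
  confounded with training in a pre/post cohort; the generator makes no
  attempt to separate them.
* The paired 2x2 chi-square is computed on the full pre-by-post table;
  published values derived from unavailable cell splits can be checked
  for convention (via phi and n) but not re-derived from margins.
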