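# dotprobe

Analysis and simulation toolkit for **individualized attention-bias
modification** delivered through a modified dot-probe task, aimed at
intervention researchers studying treatment adherence and psychological
distress (the motivating use case is antiretroviral-therapy adherence in
people living with HIV with elevated depressive symptoms).

In this class of interventions, each participant's own treatment-related
thoughts are elicited, rated pairwise for similarity, embedded in a 2D
"cognitive map", and then used as stimuli in a web-delivered dot-probe
training task: two contrasting thoughts appear after a 1000 ms fixation
cross for ~2500 ms, and a probe then replaces one of them. The probe is
**always** placed at the stimulus that is treatment approach-oriented and
neutral or positive in tone — never at a negative or avoidance-oriented
stimulus — so that, over many trials (4 blocks x 50 trials per session,
3 sessions/day over 4 weeks = 84 target sessions), attention is retrained
toward adherence-supporting thoughts. Outcomes are assessed pre/post with
reaction-time measures and standard screeners.

## What the package computes

* **Stimulus assessment** — pairwise similarity schedules
  (`pair_schedule()`), nonmetric multidimensional scaling by stress
  majorization (SMACOF) with Kruskal stress-1 and monotone (isotonic)
  disparities (`mds_embed()`), and the probe-target/distractor partition
  (`classify_for_training()`).
* **Session engine** — trial planning with the contingent probe-placement
  rule and per-block counterbalancing (`build_session_plan()`), headless
  execution against any response provider (`run_session()`), block
  feedback (`block_summary()`), the 80% tutorial gate (`tutorial_gate()`),
  protocol-adherence accounting (`protocol_adherence()`), and JSON-lines
  trial logging (`write_session_log()` / `read_session_logs()`).
* **Reaction-time pipeline** — correct-only filtering
  (`filter_correct()`), per-participant trimming of RTs beyond 1.5 SD of
  the participant's mean (`trim_outliers()`), and the pairing-type x
  assessment-period table with paired tests (`pairing_means()`,
  `accuracy_table()`).
* **Outcome statistics** — instrument scoring with published cut points
  (`phq9_score()`: bands minimal/mild/moderate/moderately-severe/severe
  and the >= 10 cutoff; `pclc_score()`: range 17–85, screen at >= 30;
  `mms_anxiety_score()`: elevated at >= 6; `adherence_category()`: VAS
  bins 1–3 = low, 4 = moderate/high), `paired_t()`, the paired-design
  effect size `d = |t| / sqrt(n)` (`cohen_d_paired()`), the 2x2
  categorical effect size `phi = sqrt(chi2 / n)` (`phi_effect()`,
  `categorical_change_test()`), `percent_reduction()`,
  `cronbach_alpha()`, and the assembled `outcome_report()`.
* **Synthetic cohorts** — `cohort_params()` / `generate_cohort()` emulate
  a small completer cohort (defaults: n = 12; baseline pairing means
  2483–2579 ms with ~700 ms between-person SD; 308–369 ms training
  reductions; ex-Gaussian trial noise; 4%/2% lapse rates; PHQ-9 baseline
  13.4 (6.8) with standardized change 1.2), and
  `parameter_recovery_suite()` runs Monte-Carlo recovery of the
  generating effect sizes through the full pipeline.

## Worked example

```r
library(dotprobe)

params <- cohort_params(seed = 2025)      # n = 12 simulated completers
cohort <- generate_cohort(params)

# RT pipeline: filter correct responses, trim +/-1.5 SD per participant,
# summarize by pairing type and assessment period
obs <- as_rt_observations(cohort$session_logs)
pmt <- pairing_means(trim_outliers(filter_correct(obs)))
format_pairing_table(pmt)
#>             pairing   baseline posttraining reduction_ms    t     p cohen_d
#> 1  positive-neutral 2682 (807)   2267 (438)          415 3.79 0.003    1.10
#> 2  negative-neutral 2690 (792)   2318 (430)          372 3.45 0.005    1.00
#> 3 positive-negative 2680 (813)   2254 (434)          425 3.83 0.003    1.11
#> 4   neutral-neutral 2627 (797)   2256 (415)          371 3.26 0.008    0.94

# Pre/post outcomes: adherence 2x2 with phi, PHQ-9 change with Cohen's d
outcome_report(cohort$surveys)
#> Outcome report (n = 12 paired participants)
#> Adherence low -> moderate/high shift: chi2 = 8.6, phi = 0.85
#> PHQ-9: 15.2 (7.6) -> 10.3 (7.4); t(11) = 3.61, d = 1.04, reduction 32%

# Individualized stimulus assessment for one participant
map <- mds_embed(to_dissimilarity(cohort$similarity[["P01"]]), seed = 1)
map
#> Cognitive map: 12 stimuli, 2 dimensions
#> Kruskal stress-1: 0.031069 after 117 iterations
```

Each formatted row reads "cohort mean (between-person SD)" in ms; the
paired `t` compares participant-level means across periods, and `cohen_d`
is `|t|/sqrt(n)`. One simulated cohort's numbers vary around the
generating values (e.g. reductions around 308–369 ms) because n = 12 is
small; `parameter_recovery_suite()` quantifies that sampling variation.

A thin command-line wrapper over the same functions lives at
`inst/cli/dotprobe-cli.R` (subcommands `simulate`, `plan-session`,
`assess-map`, `analyze-rt`, `outcomes`), each run writing a seed/config
manifest for reproducibility.

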