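test_that("cohort_params validates and rejects malformed settings", {
  p <- cohort_params()
  expect_equal(p$n_participants, 12L)
  expect_error(cohort_params(lapse_rate_baseline = 1.5),
               class = "dotprobe_input_error")
  expect_error(cohort_params(phq9_pre_sd = -1),
               class = "dotprobe_input_error")
  expect_error(cohort_params(pairing_offsets_ms = c(a = 1)),
               class = "dotprobe_input_error")

  # fuzzed parameter sets: invalid ones are always rejected before any
  # generation, valid ones always accepted
  withr::with_seed(55, {
    for (i in 1:1000) {
      field <- sample(c("lapse_rate_baseline", "timeout_rate",
                        "adherence_improve_prob", "phq9_change_sd",
                        "between_person_sd_ms", "n_participants"), 1)
      value <- sample(c(-1, -0.2, 0.3, 0.9, 2, 700), 1)
      args <- setNames(list(value), field)
      valid <- switch(field,
        n_participants = value >= 1 && value == floor(value),
        phq9_change_sd = ,
        between_person_sd_ms = value > 0,
        value >= 0 && value <= 1)
      if (valid) {
        expect_s3_class(do.call(cohort_params, args), "cohort_params")
      } else {
        expect_error(do.call(cohort_params, args),
                     class = "dotprobe_input_error")
      }
    }
  })
})

test_that("cohort generation is a pure function of params (determinism)", {
  p <- cohort_params(n_participants = 3L, seed = 321L)
  a <- generate_cohort(p)
  b <- generate_cohort(p)
  expect_identical(a$participants, b$participants)
  expect_identical(a$surveys, b$surveys)
  expect_identical(lapply(a$session_logs, `[[`, "trials"),
                   lapply(b$session_logs, `[[`, "trials"))
  expect_identical(a$similarity[[1]]$ratings, b$similarity[[1]]$ratings)
  c <- generate_cohort(cohort_params(n_participants = 3L, seed = 322L))
  expect_false(identical(a$surveys, c$surveys))
})

test_that("generated artifacts validate against their schemas", {
  coh <- generate_cohort(cohort_params(n_participants = 4L, seed = 9L))
  # inventories are valid and plan-compatible
  for (inv in coh$inventories) {
    expect_s3_class(validate_inventory(inv), "stimulus_inventory")
    part <- classify_for_training(inv)
    expect_gt(nrow(part$probe_targets), 0)
    expect_gt(nrow(part$distractors), 0)
  }
  # similarity objects pass the constructor invariants
  for (sr in coh$similarity) {
    expect_s3_class(similarity_ratings(sr$stimulus_ids, sr$ratings,
                                       sr$scale_bounds),
                    "similarity_ratings")
  }
  # session logs: complete 4 x 50 sessions, schema-identical to the
  # engine's responder-driven output
  engine_log <- fixture_session_log()
  for (l in coh$session_logs) {
    expect_s3_class(l, "session_log")
    expect_true(l$complete)
    expect_equal(nrow(l$trials), 200L)
    expect_identical(names(l$trials), names(engine_log$trials))
    expect_identical(unname(vapply(l$trials, class, character(1))),
                     unname(vapply(engine_log$trials, class, character(1))))
    expect_true(all(l$trials$correct ==
                      (l$trials$response_side == l$trials$probe_side)))
  }
  # surveys: PHQ-9 items are a faithful split of totals, in range
  expect_true(all(vapply(seq_len(nrow(coh$surveys)), function(i) {
    items <- coh$surveys$phq9_items[[i]]
    length(items) == 9 && all(items %in% 0:3) &&
      sum(items) == coh$surveys$phq9_total[i]
  }, logical(1))))
  expect_true(all(coh$surveys$phq9_total >= 0 & coh$surveys$phq9_total <= 27))
  expect_true(all(coh$surveys$vas_category %in% 1:4))
  expect_true(all(coh$surveys$pclc_total >= 17 & coh$surveys$pclc_total <= 85))
})

test_that("lapse rate zero produces all-correct trials", {
  p <- cohort_params(n_participants = 2L, lapse_rate_baseline = 0,
                     lapse_rate_post = 0, timeout_rate = 0, seed = 2L)
  coh <- generate_cohort(p, what = "trials")
  for (l in coh$session_logs) expect_true(all(l$trials$correct))
})

test_that("posttraining mean RTs fall below baseline for all pairings", {
  coh <- generate_cohort(cohort_params(seed = 7L), what = "trials")
  pmt <- pairing_means(trim_outliers(filter_correct(
    as_rt_observations(coh$session_logs))))
  expect_true(all(pmt$posttraining_mean < pmt$baseline_mean))
  expect_true(all(pmt$n == 12L))
})

test_that("noiseless similarity ratings let the embedding recover the latent map", {
  inv <- generate_inventory("P01", 12, seed = 3)
  sr <- generate_similarity(inv, seed = 4, noise_sd = 0)
  latent <- attr(sr, "latent")
  map <- mds_embed(to_dissimilarity(sr), seed = 1)
  expect_lt(procrustes_rmsd(latent, map$coordinates), 1e-3)

  # all latent points identical -> all ratings maximal
  same <- generate_similarity(inv, seed = 4,
                              latent = matrix(1, nrow(inv), 2))
  expect_true(all(same$ratings == same$scale_bounds[2]))
})

test_that("embedding stress grows with rating noise (Monte-Carlo trend)", {
  mean_stress <- vapply(c(0, 0.6, 2), function(ns) {
    mean(vapply(1:3, function(s) {
      inv <- generate_inventory("P01", 10, seed = s)
      sr <- generate_similarity(inv, seed = s + 10, noise_sd = ns)
      mds_embed(to_dissimilarity(sr), seed = 1, n_init = 2)$stress
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(mean_stress) > 0))
})

test_that("larger generating reductions yield larger recovered RT changes", {
  grid <- c(0, 150, 300, 450, 600)
  recovered <- vapply(seq_along(grid), function(gi) {
    mean(vapply(1:3, function(s) {
      p <- cohort_params(
        n_participants = 6L,
        training_reduction_mean_ms = grid[gi],
        reduction_offsets_ms = setNames(rep(0, 4),
                                        dotprobe:::PAIRING_TYPES),
        seed = 100L * gi + s)
      coh <- generate_cohort(p, what = "trials")
      pmt <- pairing_means(trim_outliers(filter_correct(
        as_rt_observations(coh$session_logs))))
      mean(pmt$delta_ms)
    }, numeric(1)))
  }, numeric(1))
  expect_gt(cor(grid, recovered, method = "spearman"), 0.95)
})

test_that("null generating effects recover changes centered on zero", {
  p <- cohort_params(training_reduction_mean_ms = 0,
                     reduction_offsets_ms = setNames(rep(0, 4),
                                                     dotprobe:::PAIRING_TYPES),
                     reduction_baseline_coupling = 0,
                     phq9_effect_d = 0)
  rec <- parameter_recovery_suite(p, n_reps = 30L, seed = 15L)
  deltas <- rec$summary[grepl("^delta_", rec$summary$quantity), ]
  expect_true(all(deltas$ci_lo < 0 & deltas$ci_hi > 0))
  d_row <- rec$summary[rec$summary$quantity == "phq9_d", ]
  # |d-hat| is non-negative by convention, so the null recovers a small
  # positive mean; it must sit well below any real effect
  expect_lt(d_row$mean_recovered, 0.5)
})
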