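test_that("protocol constants encode the training protocol", {
  pc <- protocol_constants()
  expect_equal(pc$trials_per_session, 200L)
  expect_equal(pc$total_target_sessions, 84L)
  expect_error(protocol_constants(fixation_ms = -5),
               class = "dotprobe_input_error")
})

test_that("session plans have the protocol structure and are balanced", {
  part <- classify_for_training(fixture_inventory())
  for (seed in 1:5) {
    plan <- build_session_plan(part$probe_targets, part$distractors,
                               seed = seed)
    expect_equal(nrow(plan), 200L)
    expect_equal(as.vector(table(plan$block)), rep(50L, 4))
    # full session exactly balanced across pairing types
    expect_equal(as.vector(table(plan$pairing_type)), rep(50L, 4))
    # block-level allocation is 13/13/12/12
    per_block <- table(plan$block, plan$pairing_type)
    expect_true(all(apply(per_block, 1L, function(r)
      identical(sort(unname(r)), c(12L, 12L, 13L, 13L)))))
    # left/right probe placement within block off 50/50 by at most 1
    lefts <- tapply(plan$probe_side == "left", plan$block, sum)
    expect_true(all(abs(lefts - 25) <= 1))
    # left and right stimuli always differ
    expect_true(all(plan$left_stimulus_id != plan$right_stimulus_id))
  }
})

test_that("the probe never lands on a negative or avoidance stimulus", {
  inv <- fixture_inventory()
  part <- classify_for_training(inv)
  lookup <- setNames(paste(inv$valence, inv$orientation), inv$stimulus_id)
  for (seed in 1:8) {
    plan <- build_session_plan(part$probe_targets, part$distractors,
                               seed = seed)
    probe_stim <- ifelse(plan$probe_side == "left",
                         plan$left_stimulus_id, plan$right_stimulus_id)
    labs <- lookup[probe_stim]
    expect_false(any(grepl("negative|avoidance", labs)))
    # and the probe-side member is always from the probe-target partition
    expect_true(all(probe_stim %in% part$probe_targets$stimulus_id))
    # pairing-type composition: the non-probe member matches the pair label
    other <- ifelse(plan$probe_side == "left",
                    plan$right_stimulus_id, plan$left_stimulus_id)
    ov <- sub(" .*", "", lookup[other])
    expect_true(all(ov[plan$pairing_type == "positive-negative"] == "negative"))
    expect_true(all(ov[plan$pairing_type == "negative-neutral"] == "negative"))
    expect_true(all(ov[plan$pairing_type == "neutral-neutral"] == "neutral"))
  }
})

test_that("plans are deterministic given (inventory, seed), and serialize identically", {
  part <- classify_for_training(fixture_inventory())
  a <- build_session_plan(part$probe_targets, part$distractors, seed = 99)
  b <- build_session_plan(part$probe_targets, part$distractors, seed = 99)
  expect_identical(a, b)
  expect_identical(serialize(a, NULL), serialize(b, NULL))
  c <- build_session_plan(part$probe_targets, part$distractors, seed = 100)
  expect_false(identical(a, c))
})

test_that("plans require every stimulus class", {
  inv <- fixture_inventory()
  no_neg <- classify_for_training(inv[inv$valence != "negative", ])
  expect_error(
    build_session_plan(no_neg$probe_targets, no_neg$distractors, seed = 1),
    "negative", class = "dotprobe_input_error")
  no_pos <- classify_for_training(inv[inv$valence != "positive", ])
  expect_error(
    build_session_plan(no_pos$probe_targets, no_pos$distractors, seed = 1),
    "positive", class = "dotprobe_input_error")
})

test_that("run_session records correctness, RT pass-through and feedback", {
  # perfect responder: 100% accuracy, zero feedback, fixed RT recorded
  log <- fixture_session_log(rt = 500)
  expect_true(log$complete)
  expect_equal(mean(log$trials$correct), 1)
  expect_equal(sum(log$trials$feedback_emitted), 0L)
  expect_true(all(log$trials$rt_ms == 500))
  expect_true(all(log$trials$probe_onset_ms == 3500))

  # anti-responder: 0% accuracy, feedback on all 200 trials
  anti <- fixture_session_log(wrong_trials = 1:200)
  expect_equal(mean(anti$trials$correct), 0)
  expect_equal(sum(anti$trials$feedback_emitted), 200L)
})

test_that("responder failure yields a partial, incomplete session", {
  log <- fixture_session_log(fail_at = 151)
  expect_false(log$complete)
  expect_equal(nrow(log$trials), 150L)
  expect_match(log$incomplete_reason, "trial 151")
})

test_that("timeouts are recorded as no-response incorrect trials", {
  part <- classify_for_training(fixture_inventory())
  plan <- build_session_plan(part$probe_targets, part$distractors, seed = 2)
  slow <- function(spec) list(response_side = spec$probe_side, rt_ms = 9000)
  log <- run_session(plan, slow)
  expect_true(all(log$trials$response_side == "none"))
  expect_true(all(is.na(log$trials$rt_ms)))
  expect_false(any(log$trials$correct))
})

test_that("block_summary averages correct-trial RTs only", {
  block <- data.frame(
    correct = rep(c(TRUE, FALSE), each = 5),
    rt_ms = rep(c(400, 900), each = 5)
  )
  s <- block_summary(block)
  expect_equal(s$mean_rt_ms, 400)
  expect_equal(s$accuracy_rate, 0.5)

  all_ok <- data.frame(correct = rep(TRUE, 50), rt_ms = rep(600, 50))
  expect_equal(block_summary(all_ok), list(mean_rt_ms = 600,
                                           accuracy_rate = 1))
  # 47/50 correct reproduces the 0.94 accuracy scale
  b47 <- data.frame(correct = rep(c(TRUE, FALSE), c(47, 3)), rt_ms = 500)
  expect_equal(block_summary(b47)$accuracy_rate, 0.94)
  none_ok <- data.frame(correct = rep(FALSE, 10), rt_ms = NA_real_)
  expect_true(is.na(block_summary(none_ok)$mean_rt_ms))
  expect_equal(block_summary(none_ok)$accuracy_rate, 0)
})

test_that("tutorial gate is inclusive at the 80% threshold", {
  expect_true(tutorial_gate(fixture_session_log(wrong_trials = 1:40))$pass)
  expect_false(tutorial_gate(fixture_session_log(wrong_trials = 1:41))$pass)
  expect_true(tutorial_gate(fixture_session_log())$pass)
  incomplete <- fixture_session_log(fail_at = 10)
  gate <- tutorial_gate(incomplete)
  expect_false(gate$pass)
  expect_equal(gate$reason, "incomplete")
})

test_that("protocol adherence counts only complete 4-block sessions", {
  complete <- fixture_session_log()
  partial <- fixture_session_log(fail_at = 151)  # 3 blocks finished
  logs <- c(rep(list(complete), 83), list(partial))
  adh <- protocol_adherence(logs)
  expect_equal(adh$sessions_completed, 83L)
  expect_equal(adh$target, 84L)

  expect_equal(protocol_adherence(list())$sessions_completed, 0L)
  adh48 <- protocol_adherence(rep(list(complete), 48))
  expect_equal(adh48$sessions_completed, 48L)
  expect_equal(adh48$fraction_of_target, 48 / 84)
})

test_that("session logs round-trip through JSON lines bit-exactly", {
  log <- fixture_session_log(wrong_trials = c(3, 77), seed = 6)
  log$trials$rt_ms <- log$trials$rt_ms + 0.123456789  # non-integer RTs
  f <- withr::local_tempfile(fileext = ".jsonl")
  write_session_log(log, f)
  back <- read_session_log(f)
  expect_identical(back$participant_id, log$participant_id)
  expect_identical(back$assessment_period, log$assessment_period)
  expect_identical(back$complete, log$complete)
  rownames(log$trials) <- NULL
  expect_equal(back$trials, log$trials, tolerance = 0)
  # writing the read-back log reproduces the file byte-for-byte
  f2 <- withr::local_tempfile(fileext = ".jsonl")
  write_session_log(back, f2)
  expect_identical(readLines(f), readLines(f2))
})

test_that("corrupted session-log lines are reported by line number", {
  log <- fixture_session_log()
  f <- withr::local_tempfile(fileext = ".jsonl")
  write_session_log(log, f)
  lines <- readLines(f)
  lines[5] <- substr(lines[5], 1, 20)  # truncate -> invalid JSON
  writeLines(lines, f)
  expect_error(read_session_log(f), "line.*5",
               class = "dotprobe_schema_error")
})

test_that("a directory of logs is read back in full", {
  dir <- withr::local_tempdir()
  for (i in 1:6) {
    write_session_log(fixture_session_log(seed = i),
                      file.path(dir, sprintf("s%02d.jsonl", i)))
  }
  logs <- read_session_logs(dir)
  expect_length(logs, 6L)
  expect_true(all(vapply(logs, function(l) l$complete, logical(1))))
})
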