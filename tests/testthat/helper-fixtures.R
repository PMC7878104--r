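# shared fixtures: small labelled inventories, deterministic responders,
# and toy observation tables built in code

fixture_inventory <- function() {
  stimulus_inventory(
    stimulus_id = sprintf("s%d", 1:8),
    text = c("meds keep me strong", "I stay on schedule",
             "pills by the coffee maker", "bottle has a white cap",
             "bus stops at the pharmacy", "I dread refill day",
             "side effects scare me", "meds remind me I am sick"),
    valence = c("positive", "positive", "neutral", "neutral", "neutral",
                "negative", "negative", "negative"),
    orientation = c("approach", "approach", "approach", "neutral",
                    "neutral", "avoidance", "avoidance", "avoidance")
  )
}

# responder answering the probe side with fixed RT; optional error trials
fixture_responder <- function(rt = 500, wrong_trials = integer(0),
                              fail_at = NA_integer_) {
  count <- 0L
  function(spec) {
    count <<- count + 1L
    if (!is.na(fail_at) && count == fail_at) stop("responder lost connection")
    side <- spec$probe_side
    if (count %in% wrong_trials) {
      side <- setdiff(c("left", "right"), side)
    }
    list(response_side = side, rt_ms = rt)
  }
}

fixture_session_log <- function(wrong_trials = integer(0), rt = 500,
                                fail_at = NA_integer_, seed = 1L,
                                participant_id = "P01",
                                assessment_period = "baseline") {
  part <- classify_for_training(fixture_inventory())
  plan <- build_session_plan(part$probe_targets, part$distractors,
                             seed = seed)
  run_session(plan, fixture_responder(rt, wrong_trials, fail_at),
              participant_id = participant_id,
              assessment_period = assessment_period, seed = seed)
}

# observation table builder for RT-pipeline tests
fixture_obs <- function(participant_id, period, pairing, rts,
                        correct = TRUE) {
  data.frame(
    participant_id = participant_id, assessment_period = period,
    pairing_type = pairing, rt_ms = rts,
    correct = rep_len(correct, length(rts)), stringsAsFactors = FALSE
  )
}

# exact 2D-Euclidean dissimilarity from a generating configuration
fixture_planar_dissim <- function(n, seed) {
  X <- withr::with_seed(seed, matrix(rnorm(2 * n), n, 2))
  list(X = X, D = as.matrix(dist(X)))
}
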