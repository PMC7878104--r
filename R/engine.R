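#' Protocol constants for the attention-training task
#'
#' Timing and structure of the modified dot-probe protocol: a 1000 ms
#' central fixation, ~2500 ms simultaneous exposure of two contrasting
#' thought stimuli, then a probe at one stimulus location until response.
#' Sessions are 4 blocks of 50 trials; the program asks for 3 sessions a
#' day over 28 days (84 sessions); the tutorial requires 80% accuracy
#' before training proper.
#'
#' @param fixation_ms fixation-cross duration (default 1000).
#' @param stimulus_exposure_ms stimulus-pair exposure (default 2500).
#' @param trials_per_block trials per block (default 50).
#' @param blocks_per_session blocks per session (default 4).
#' @param tutorial_accuracy_gate minimum tutorial accuracy, inclusive
#'   (default 0.80).
#' @param sessions_per_day_target target sessions per day (default 3).
#' @param program_days program length in days (default 28).
#' @param response_timeout_ms response window after probe onset; a slower
#'   (or absent) response is recorded as a timeout (default 5000).
#' @param inter_trial_interval_ms pause between trials (default 0).
#' @return List of class `protocol_constants`; includes the derived
#'   `total_target_sessions` and `trials_per_session`.
#' @export
protocol_constants <- function(fixation_ms = 1000,
                               stimulus_exposure_ms = 2500,
                               trials_per_block = 50L,
                               blocks_per_session = 4L,
                               tutorial_accuracy_gate = 0.80,
                               sessions_per_day_target = 3L,
                               program_days = 28L,
                               response_timeout_ms = 5000,
                               inter_trial_interval_ms = 0) {
  pc <- list(
    fixation_ms = fixation_ms,
    stimulus_exposure_ms = stimulus_exposure_ms,
    trials_per_block = as.integer(trials_per_block),
    blocks_per_session = as.integer(blocks_per_session),
    tutorial_accuracy_gate = tutorial_accuracy_gate,
    sessions_per_day_target = as.integer(sessions_per_day_target),
    program_days = as.integer(program_days),
    response_timeout_ms = response_timeout_ms,
    inter_trial_interval_ms = inter_trial_interval_ms
  )
  for (nm in setdiff(names(pc), "inter_trial_interval_ms")) {
    dp_assert(is.numeric(pc[[nm]]) && length(pc[[nm]]) == 1L && pc[[nm]] > 0,
              "%s must be a positive scalar", nm)
  }
  dp_assert(is_prob(pc$tutorial_accuracy_gate),
            "tutorial_accuracy_gate must be in [0, 1]")
  dp_assert(pc$inter_trial_interval_ms >= 0,
            "inter_trial_interval_ms must be non-negative")
  pc$trials_per_session <- pc$trials_per_block * pc$blocks_per_session
  pc$total_target_sessions <- pc$sessions_per_day_target * pc$program_days
  structure(pc, class = "protocol_constants")
}

# pool lookup for one pairing type: which valence carries the probe and
# which valence is the non-probe member
pairing_roles <- function(pairing_type) {
  switch(pairing_type,
    "positive-neutral"  = list(probe = "positive", other = "neutral"),
    "negative-neutral"  = list(probe = "neutral",  other = "negative"),
    "positive-negative" = list(probe = "positive", other = "negative"),
    "neutral-neutral"   = list(probe = "neutral",  other = "neutral"),
    dp_stop("unknown pairing type: %s", pairing_type)
  )
}

#' Build a full training-session plan of trial specifications
#'
#' Plans one 4-block x 50-trial session.  Each trial shows two contrasting
#' stimuli and the probe always replaces the treatment approach-oriented
#' stimulus with neutral or positive emotional tone — never a negative or
#' avoidance-oriented one; this contingency is what retrains attention.
#' The four pairing types are allocated 13/13/12/12 per block, with the
#' types receiving 13 rotated across blocks (and the rotation offset by
#' seed) so a complete session is exactly balanced at 50 trials per type.
#' The probe-target's left/right position is counterbalanced within block.
#'
#' @param probe_targets,distractors inventory data.frames as returned by
#'   [classify_for_training()].
#' @param constants a [protocol_constants()] object.
#' @param seed integer seed; plans are deterministic given
#'   (inventory, seed).
#' @return A `data.frame` of class `session_plan` with columns
#'   `trial_index`, `block`, `pairing_type`, `left_stimulus_id`,
#'   `right_stimulus_id`, `probe_side`.
#' @export
build_session_plan <- function(probe_targets, distractors,
                               constants = protocol_constants(), seed = 1L) {
  dp_assert(inherits(constants, "protocol_constants"),
            "constants must be a protocol_constants object")
  all_stim <- rbind(as.data.frame(probe_targets), as.data.frame(distractors))
  dp_assert(nrow(all_stim) >= 2L, "need at least two stimuli")
  pools <- list(
    pos_target = probe_targets$stimulus_id[probe_targets$valence == "positive"],
    neu_target = probe_targets$stimulus_id[probe_targets$valence == "neutral"],
    negative   = all_stim$stimulus_id[all_stim$valence == "negative"],
    neutral    = all_stim$stimulus_id[all_stim$valence == "neutral"]
  )
  dp_assert(length(pools$pos_target) >= 1L,
            "inventory must contain a positive-valence probe target")
  dp_assert(length(pools$neu_target) >= 1L,
            "inventory must contain a neutral-valence probe target")
  dp_assert(length(pools$negative) >= 1L,
            "inventory must contain a negative-valence stimulus")
  dp_assert(length(pools$neutral) >= 2L,
            "inventory must contain two neutral-valence stimuli")

  n_types <- length(PAIRING_TYPES)
  tpb <- constants$trials_per_block
  base <- tpb %/% n_types
  n_heavy <- tpb %% n_types                    # types getting base+1 trials
  rot <- as.integer(as.numeric(seed) %% n_types)

  with_seed(sub_seed(seed, 1L, stream = 11L), {
    blocks <- lapply(seq_len(constants$blocks_per_session), function(b) {
      heavy <- ((rot + b - 1L + seq_len(n_heavy) - 1L) %% n_types) + 1L
      counts <- rep(base, n_types)
      counts[heavy] <- counts[heavy] + 1L
      rows <- lapply(seq_len(n_types), function(ti) {
        type <- PAIRING_TYPES[ti]
        k <- counts[ti]
        roles <- pairing_roles(type)
        probe_pool <- switch(roles$probe,
                             positive = pools$pos_target,
                             neutral = pools$neu_target)
        other_pool <- switch(roles$other,
                             negative = pools$negative,
                             neutral = pools$neutral)
        probe_stim <- sample(probe_pool, k, replace = TRUE)
        other_stim <- vapply(probe_stim, function(p) {
          cand <- setdiff(other_pool, p)
          if (length(cand) == 1L) cand else sample(cand, 1L)
        }, character(1))
        # counterbalance: alternate which side gets the extra trial among
        # heavy types so the block total stays 50/50 (or within 1)
        n_left <- if (k %% 2L == 0L) k %/% 2L
                  else k %/% 2L + (which(heavy == ti) %% 2L)
        sides <- sample(c(rep("left", n_left), rep("right", k - n_left)))
        data.frame(
          block = b, pairing_type = type,
          left_stimulus_id = ifelse(sides == "left", probe_stim, other_stim),
          right_stimulus_id = ifelse(sides == "left", other_stim, probe_stim),
          probe_side = sides,
          stringsAsFactors = FALSE
        )
      })
      block_df <- do.call(rbind, rows)
      block_df[sample.int(nrow(block_df)), , drop = FALSE]
    })
    plan <- do.call(rbind, blocks)
    plan <- cbind(trial_index = seq_len(nrow(plan)), plan)
    rownames(plan) <- NULL
    class(plan) <- c("session_plan", "data.frame")
    attr(plan, "seed") <- as.integer(seed)
    plan
  })
}

#' Execute a planned session against a response provider
#'
#' Runs the simulated per-trial timeline (fixation, stimulus exposure,
#' probe until response) headlessly.  The responder is any function taking
#' one plan row and returning `list(response_side =, rt_ms =)`;
#' `response_side = "none"` or an RT beyond the timeout is a timeout,
#' counted incorrect.  Error feedback (the audible alert in the deployed
#' app) is recorded as a boolean event on incorrect trials.
#'
#' @param plan a [build_session_plan()] result.
#' @param responder function of one trial spec; see Details.
#' @param constants a [protocol_constants()] object.
#' @param participant_id,session_index,assessment_period session metadata;
#'   `assessment_period` is one of `"baseline"`, `"training"`,
#'   `"posttraining"`.
#' @param seed seed recorded in the log (provenance only).
#' @return A `session_log`: list with metadata, a `trials` data.frame
#'   (plan columns plus `probe_onset_ms`, `response_side`, `rt_ms`,
#'   `correct`, `feedback_emitted`), and `complete` flag.  If the
#'   responder fails mid-session the partial log is returned with
#'   `complete = FALSE` and an `incomplete_reason`.
#' @export
run_session <- function(plan, responder, constants = protocol_constants(),
                        participant_id = "sim", session_index = 1L,
                        assessment_period = "training", seed = NA_integer_) {
  dp_assert(is.function(responder), "responder must be a function")
  dp_assert(assessment_period %in% c(PERIOD_LEVELS, "training"),
            "invalid assessment_period")
  n <- nrow(plan)
  probe_onset <- constants$fixation_ms + constants$stimulus_exposure_ms
  response_side <- character(n)
  rt_ms <- rep(NA_real_, n)
  failed_at <- NA_integer_
  for (i in seq_len(n)) {
    res <- tryCatch(responder(plan[i, , drop = FALSE]), error = function(e) e)
    if (inherits(res, "error")) { failed_at <- i; break }
    side <- res$response_side %||% "none"
    rt <- res$rt_ms %||% NA_real_
    if (identical(side, "none") || !is.finite(rt) ||
        rt > constants$response_timeout_ms) {
      side <- "none"; rt <- NA_real_
    }
    dp_assert(side %in% c("left", "right", "none"),
              "responder returned invalid side '%s'", side)
    response_side[i] <- side
    rt_ms[i] <- rt
  }
  done <- if (is.na(failed_at)) n else failed_at - 1L
  trials <- plan[seq_len(done), , drop = FALSE]
  trials$probe_onset_ms <- rep(probe_onset, done)
  trials$response_side <- response_side[seq_len(done)]
  trials$rt_ms <- rt_ms[seq_len(done)]
  trials$correct <- trials$response_side == trials$probe_side
  trials$feedback_emitted <- !trials$correct
  class(trials) <- "data.frame"
  attr(trials, "seed") <- NULL
  rownames(trials) <- NULL
  structure(
    list(
      participant_id = participant_id,
      session_index = as.integer(session_index),
      assessment_period = assessment_period,
      seed = as.integer(seed),
      constants = constants,
      trials = trials,
      complete = is.na(failed_at) && done == constants$trials_per_session,
      incomplete_reason = if (!is.na(failed_at))
        sprintf("responder failed at trial %d", failed_at) else NULL
    ),
    class = "session_log"
  )
}

#' Summarize one block: mean correct-response RT and accuracy
#'
#' Reproduces the end-of-block feedback screen: accuracy is
#' correct/total; mean RT is computed over correct responses only (no
#' correct responses gives an absent RT).
#'
#' @param block data.frame of trial records from one block.
#' @return list with `mean_rt_ms` (NA if no correct trial) and
#'   `accuracy_rate`.
#' @export
block_summary <- function(block) {
  dp_assert(is.data.frame(block) && nrow(block) > 0L,
            "block must be a non-empty data.frame of trial records")
  acc <- mean(block$correct)
  rts <- block$rt_ms[block$correct]
  list(
    mean_rt_ms = if (length(rts)) mean(rts) else NA_real_,
    accuracy_rate = acc
  )
}

#' Tutorial accuracy gate
#'
#' Participants must reach the tutorial accuracy threshold (inclusive)
#' before starting training proper.
#'
#' @param tutorial_log a complete `session_log` from the tutorial session.
#' @param constants a [protocol_constants()] object.
#' @return list with `pass` (logical), `accuracy`, and `reason`
#'   (`"incomplete"` when the log is not a full session).
#' @export
tutorial_gate <- function(tutorial_log, constants = protocol_constants()) {
  dp_assert(inherits(tutorial_log, "session_log"),
            "tutorial_log must be a session_log")
  if (!isTRUE(tutorial_log$complete)) {
    return(list(pass = FALSE, accuracy = NA_real_, reason = "incomplete"))
  }
  acc <- mean(tutorial_log$trials$correct)
  list(pass = acc >= constants$tutorial_accuracy_gate, accuracy = acc,
       reason = NULL)
}

#' Count completed sessions against the protocol target
#'
#' A session counts only when all blocks were finished; partial sessions
#' are excluded at block granularity.
#'
#' @param logs list of `session_log` objects from one participant.
#' @param constants a [protocol_constants()] object.
#' @return list with `sessions_completed`, `target`
#'   (`total_target_sessions`), and `fraction_of_target`.
#' @export
protocol_adherence <- function(logs, constants = protocol_constants()) {
  dp_assert(is.list(logs), "logs must be a list of session_log objects")
  completed <- sum(vapply(logs, function(l) {
    inherits(l, "session_log") && isTRUE(l$complete) &&
      nrow(l$trials) == constants$trials_per_session
  }, logical(1)))
  list(
    sessions_completed = completed,
    target = constants$total_target_sessions,
    fraction_of_target = completed / constants$total_target_sessions
  )
}

#' Construct a simulated responder
#'
#' Returns a responder closure for [run_session()] that answers the probe
#' side with probability `1 - lapse_rate` (a lapse picks the wrong side),
#' times out with probability `timeout_rate`, and draws RTs from an
#' ex-Gaussian shifted to the supplied per-pairing mean.
#'
#' @param mean_rt_ms named numeric: target mean RT per pairing type (a
#'   single unnamed value recycles to all four).
#' @param sigma_ms,tau_ms ex-Gaussian Gaussian SD and exponential mean.
#' @param lapse_rate probability of answering the wrong side.
#' @param timeout_rate probability of no response.
#' @param seed integer seed making the responder deterministic.
#' @return function usable as `responder` in [run_session()].
#' @export
simulated_responder <- function(mean_rt_ms, sigma_ms = 150, tau_ms = 200,
                                lapse_rate = 0.04, timeout_rate = 0,
                                seed = 1L) {
  if (is.null(names(mean_rt_ms))) {
    mean_rt_ms <- setNames(rep(mean_rt_ms[1L], length(PAIRING_TYPES)),
                           PAIRING_TYPES)
  }
  dp_assert(all(PAIRING_TYPES %in% names(mean_rt_ms)),
            "mean_rt_ms must cover all four pairing types")
  dp_assert(is_prob(lapse_rate) && is_prob(timeout_rate),
            "lapse_rate and timeout_rate must be probabilities")
  counter <- 0L
  function(spec) {
    counter <<- counter + 1L
    with_seed(sub_seed(seed, counter, stream = 17L), {
      if (runif(1) < timeout_rate) {
        return(list(response_side = "none", rt_ms = NA_real_))
      }
      side <- if (runif(1) < lapse_rate) {
        setdiff(c("left", "right"), spec$probe_side)
      } else {
        spec$probe_side
      }
      rt <- rexgauss(1L, mean = mean_rt_ms[[spec$pairing_type]],
                     sigma = sigma_ms, tau = tau_ms)
      list(response_side = side, rt_ms = rt)
    })
  }
}
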