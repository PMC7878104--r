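# Synthetic cohort generator: reproducible participants, inventories,
# similarity ratings, assessment trial logs and surveys with the
# statistical structure of a small individualized attention-training
# cohort.  Defaults are anchored to the target study conditions (n = 12
# completers; pairing-type baseline RT means 2483-2579 ms with ~700 ms
# between-person SD; 308-369 ms posttraining reductions; 94-98% accuracy;
# PHQ-9 13.4 (6.8) at baseline with a standardized change of 1.2).

#' Draw ex-Gaussian reaction times
#'
#' The ex-Gaussian (normal + exponential) is the standard generative model
#' for right-skewed RT distributions.  Parameterized here by the target
#' *mean* for convenience: draws are
#' `N(mean - tau, sigma) + Exp(1/tau)`, so `E[rt] = mean`.
#'
#' @param n number of draws.
#' @param mean target mean in ms.
#' @param sigma Gaussian SD in ms.
#' @param tau exponential mean (skew) in ms.
#' @param floor_ms lower truncation guarding against non-physical RTs.
#' @return numeric vector of length `n`.
#' @export
rexgauss <- function(n, mean, sigma = 150, tau = 200, floor_ms = 200) {
  dp_assert(sigma > 0 && tau > 0, "sigma and tau must be positive")
  pmax(rnorm(n, mean - tau, sigma) + rexp(n, 1 / tau), floor_ms)
}

#' Parameters of a synthetic training cohort
#'
#' All defaults describe the emulated study conditions; every field is
#' overridable.  RT structure: person baseline intercepts are
#' `N(rt_baseline_mean_ms, between_person_sd_ms)`; pairing-type offsets
#' shift the four pairing means; training reductions are
#' `training_reduction_mean_ms + reduction_offsets_ms` plus a component
#' proportional to the person's baseline deviation
#' (`reduction_baseline_coupling`), which reproduces the shrunken
#' posttraining between-person SD seen in practice (slower people improve
#' more).  Trial noise is ex-Gaussian; errors are independent lapses.
#'
#' @param n_participants cohort size (default 12).
#' @param rt_baseline_mean_ms grand baseline mean RT (default 2550).
#' @param between_person_sd_ms SD of person intercepts (default 700).
#' @param pairing_offsets_ms named offsets of the four pairing types from
#'   the grand mean, ms.
#' @param training_reduction_mean_ms mean pre-to-post RT reduction
#'   (default 330).
#' @param reduction_offsets_ms named per-pairing offsets to the reduction.
#' @param training_reduction_sd_ms between-person SD of the reduction's
#'   idiosyncratic component (default 80).
#' @param reduction_baseline_coupling fraction of a person's baseline
#'   deviation removed by training (default 0.45).
#' @param exgauss_sigma_ms,exgauss_tau_ms within-person trial noise.
#' @param lapse_rate_baseline,lapse_rate_post probability of an incorrect
#'   response per trial (defaults 0.04 and 0.02).
#' @param timeout_rate probability of a non-response per trial.
#' @param phq9_pre_mean,phq9_pre_sd baseline PHQ-9 distribution (13.4,
#'   6.8), truncated to 0-27.
#' @param phq9_effect_d generating standardized change (default 1.2).
#' @param phq9_change_sd SD of the person-level PHQ-9 change (default 4;
#'   with d = 1.2 this puts the mean change at 4.8 points).
#' @param adherence_pre_low_prob probability of low adherence at baseline
#'   (default 5/12).
#' @param adherence_improve_prob probability a low adherer moves to
#'   moderate/high by posttraining (default 0.4).
#' @param adherence_worsen_prob probability of the reverse transition
#'   (default 0).
#' @param n_stimuli stimuli per participant inventory (default 12).
#' @param similarity_scale rating-scale bounds (default `c(1, 9)`).
#' @param similarity_noise_sd rating noise SD (default 0.5).
#' @param seed master seed; all generation is a pure function of the
#'   parameter object including this seed.
#' @return list of class `cohort_params`.
#' @export
cohort_params <- function(n_participants = 12L,
                          rt_baseline_mean_ms = 2550,
                          between_person_sd_ms = 700,
                          pairing_offsets_ms = c(
                            "positive-neutral" = 3,
                            "negative-neutral" = 29,
                            "positive-negative" = 11,
                            "neutral-neutral" = -67),
                          training_reduction_mean_ms = 330,
                          reduction_offsets_ms = c(
                            "positive-neutral" = 23,
                            "negative-neutral" = -6,
                            "positive-negative" = 39,
                            "neutral-neutral" = -22),
                          training_reduction_sd_ms = 80,
                          reduction_baseline_coupling = 0.45,
                          exgauss_sigma_ms = 150,
                          exgauss_tau_ms = 200,
                          lapse_rate_baseline = 0.04,
                          lapse_rate_post = 0.02,
                          timeout_rate = 0.005,
                          phq9_pre_mean = 13.4,
                          phq9_pre_sd = 6.8,
                          phq9_effect_d = 1.2,
                          phq9_change_sd = 4,
                          adherence_pre_low_prob = 5 / 12,
                          adherence_improve_prob = 0.4,
                          adherence_worsen_prob = 0,
                          n_stimuli = 12L,
                          similarity_scale = c(1, 9),
                          similarity_noise_sd = 0.5,
                          seed = 1L) {
  p <- as.list(environment())
  dp_assert(is_count(p$n_participants), "n_participants must be a count")
  dp_assert(p$between_person_sd_ms > 0 && p$training_reduction_sd_ms > 0 &&
              p$phq9_pre_sd > 0 && p$phq9_change_sd > 0,
            "all SD parameters must be positive")
  for (nm in c("lapse_rate_baseline", "lapse_rate_post", "timeout_rate",
               "adherence_pre_low_prob", "adherence_improve_prob",
               "adherence_worsen_prob")) {
    dp_assert(is_prob(p[[nm]]), "%s must be a probability in [0, 1]", nm)
  }
  for (nm in c("pairing_offsets_ms", "reduction_offsets_ms")) {
    dp_assert(all(PAIRING_TYPES %in% names(p[[nm]])),
              "%s must be named with all four pairing types", nm)
    p[[nm]] <- p[[nm]][PAIRING_TYPES]
  }
  dp_assert(is_count(p$n_stimuli) && p$n_stimuli >= 6,
            "n_stimuli must be at least 6 to cover all stimulus classes")
  dp_assert(p$similarity_noise_sd >= 0, "similarity_noise_sd must be >= 0")
  structure(p, class = "cohort_params")
}

# short generic thought templates per (valence, orientation) class
STIMULUS_TEMPLATES <- list(
  "positive.approach" = c("taking my meds keeps me strong",
                          "I feel in control when I stay on schedule",
                          "my health is worth the routine",
                          "each dose is a step toward my goals"),
  "neutral.approach" = c("I keep my pills next to my keys",
                         "refill day is on my calendar",
                         "I take my dose with breakfast"),
  "neutral.neutral" = c("the pharmacy is on my bus route",
                        "my bottle has a white cap",
                        "the clinic waiting room has plants"),
  "negative.avoidance" = c("the pills remind me I am sick",
                           "I dread someone seeing my meds",
                           "side effects make me want to skip",
                           "thinking about treatment stresses me out")
)

#' Generate one participant's stimulus inventory
#'
#' Produces a labelled inventory covering all stimulus classes the
#' training plan requires: positive/approach and neutral probe targets
#' plus negative/avoidance distractors, in roughly a 1:1:1 ratio of
#' positive, neutral and negative valence.
#'
#' @param participant_id identifier used to prefix stimulus ids.
#' @param n_stimuli inventory size, at least 6.
#' @param seed integer seed.
#' @return a [stimulus_inventory()].
#' @export
generate_inventory <- function(participant_id, n_stimuli = 12L, seed = 1L) {
  dp_assert(is_count(n_stimuli) && n_stimuli >= 6, "n_stimuli must be >= 6")
  base <- n_stimuli %/% 4L
  counts <- c("positive.approach" = base, "neutral.approach" = base,
              "neutral.neutral" = base, "negative.avoidance" = base)
  extra <- n_stimuli - sum(counts)
  if (extra > 0) {
    grow <- rep(names(counts), length.out = extra)
    for (g in grow) counts[g] <- counts[g] + 1L
  }
  rows <- with_seed(seed, {
    do.call(rbind, lapply(names(counts), function(cls) {
      parts <- strsplit(cls, ".", fixed = TRUE)[[1L]]
      k <- counts[[cls]]
      templ <- sample(STIMULUS_TEMPLATES[[cls]], k, replace = TRUE)
      data.frame(valence = parts[1L], orientation = parts[2L],
                 text = paste0(templ, " (", seq_len(k), ")"),
                 stringsAsFactors = FALSE)
    }))
  })
  stimulus_inventory(
    stimulus_id = sprintf("%s_s%02d", participant_id, seq_len(nrow(rows))),
    text = paste0(participant_id, ": ", rows$text),
    valence = rows$valence,
    orientation = rows$orientation
  )
}

#' Generate similarity ratings from a latent 2D configuration
#'
#' Places each stimulus at a latent 2D position (class-specific cluster
#' centres plus seeded jitter, or positions supplied by the caller), maps
#' pairwise distances linearly onto the rating scale (maximum distance to
#' `s_min`, zero distance to `s_max`), and adds optional rating noise.
#' With zero noise the dissimilarities are an exact scaled Euclidean
#' geometry, so [mds_embed()] can be tested for configuration recovery.
#'
#' @param inventory a [stimulus_inventory()] with at least 3 stimuli.
#' @param seed integer seed.
#' @param scale_bounds rating-scale bounds (default `c(1, 9)`).
#' @param noise_sd SD of additive rating noise (default 0).
#' @param latent optional n x 2 matrix of latent positions.
#' @return a [similarity_ratings()] object with the latent configuration
#'   attached as attribute `"latent"`.
#' @export
generate_similarity <- function(inventory, seed = 1L, scale_bounds = c(1, 9),
                                noise_sd = 0, latent = NULL) {
  inv <- validate_inventory(inventory)
  n <- nrow(inv)
  dp_assert(n >= 3L, "need at least 3 stimuli")
  centres <- rbind(
    "positive.approach" = c(2, 1), "neutral.approach" = c(1, -1),
    "neutral.neutral" = c(0, -2), "negative.avoidance" = c(-2, 1)
  )
  with_seed(sub_seed(seed, 2L, stream = 23L), {
    if (is.null(latent)) {
      cls <- paste(inv$valence, inv$orientation, sep = ".")
      cls[!cls %in% rownames(centres)] <- "neutral.neutral"
      latent <- centres[cls, , drop = FALSE] +
        matrix(rnorm(2L * n, 0, 0.5), n, 2L)
    }
    latent <- as.matrix(latent)
    dp_assert(nrow(latent) == n && ncol(latent) == 2L,
              "latent must be n x 2")
    d <- as.matrix(dist(latent))
    dmax <- max(d)
    s_min <- scale_bounds[1]; s_max <- scale_bounds[2]
    ratings <- if (dmax == 0) {
      matrix(s_max, n, n)  # coincident latent points: all ratings maximal
    } else {
      s_max - (s_max - s_min) * d / dmax
    }
    if (noise_sd > 0) {
      noise <- matrix(rnorm(n * n, 0, noise_sd), n, n)
      noise <- (noise + t(noise)) / 2
      ratings <- ratings + noise
      ratings <- pmin(pmax(ratings, s_min), s_max)
      diag(ratings) <- s_max
    }
    sr <- similarity_ratings(inv$stimulus_id, ratings, scale_bounds)
    attr(sr, "latent") <- latent
    sr
  })
}

# vectorized session simulation used for cohort-scale generation; emits a
# session_log schema-identical to run_session() output
simulate_session <- function(plan, mean_rt_by_pairing, params, lapse_rate,
                             constants, participant_id, session_index,
                             assessment_period, seed) {
  n <- nrow(plan)
  with_seed(seed, {
    rt <- rexgauss(n, mean_rt_by_pairing[plan$pairing_type],
                   params$exgauss_sigma_ms, params$exgauss_tau_ms)
    lapse <- runif(n) < lapse_rate
    timeout <- runif(n) < params$timeout_rate
    side <- ifelse(lapse,
                   ifelse(plan$probe_side == "left", "right", "left"),
                   plan$probe_side)
    side[timeout] <- "none"
    rt[timeout] <- NA_real_
    trials <- as.data.frame(plan)
    attr(trials, "seed") <- NULL
    rownames(trials) <- NULL
    trials$probe_onset_ms <-
      constants$fixation_ms + constants$stimulus_exposure_ms
    trials$response_side <- side
    trials$rt_ms <- rt
    trials$correct <- side == plan$probe_side
    trials$feedback_emitted <- !trials$correct
    structure(
      list(participant_id = participant_id,
           session_index = as.integer(session_index),
           assessment_period = assessment_period,
           seed = as.integer(seed), constants = constants, trials = trials,
           complete = n == constants$trials_per_session,
           incomplete_reason = NULL),
      class = "session_log"
    )
  })
}

# deterministic split of an instrument total into item responses: start
# from the even floor, then add the remainder to seeded random items
split_total <- function(total, n_items, item_min, item_max) {
  total <- as.integer(round(total))
  total <- min(max(total, n_items * item_min), n_items * item_max)
  items <- rep(item_min + (total - n_items * item_min) %/% n_items, n_items)
  r <- total - sum(items)
  while (r > 0) {
    room <- which(items < item_max)
    bump <- sample(room, min(r, length(room)))
    items[bump] <- items[bump] + 1L
    r <- total - sum(items)
  }
  items
}

#' Generate a full synthetic cohort
#'
#' Produces, per participant: a stimulus inventory, similarity ratings,
#' baseline and posttraining assessment trial logs (one complete 200-trial
#' session each), and baseline/posttraining survey batteries.  The whole
#' cohort is a pure function of `params` (including `params$seed`).
#'
#' @param params a [cohort_params()] object.
#' @param what which artifact groups to generate (subset of
#'   `"inventories"`, `"similarity"`, `"trials"`, `"surveys"`); trimming
#'   generation to what a study needs keeps large simulation sweeps fast.
#' @return list of class `synthetic_cohort` with elements `params`,
#'   `participants` (data.frame of latent person parameters),
#'   `inventories`, `similarity` (named lists), `session_logs` (list),
#'   and `surveys` (data.frame, one row per participant-period).
#' @export
generate_cohort <- function(params = cohort_params(),
                            what = c("inventories", "similarity", "trials",
                                     "surveys")) {
  dp_assert(inherits(params, "cohort_params"),
            "params must be a cohort_params object")
  what <- match.arg(what, several.ok = TRUE)
  if ("trials" %in% what || "similarity" %in% what) {
    what <- union(what, "inventories")
  }
  np <- params$n_participants
  ids <- sprintf("P%02d", seq_len(np))
  constants <- protocol_constants()

  participants <- with_seed(sub_seed(params$seed, 0L, stream = 1L), {
    b <- rnorm(np, params$rt_baseline_mean_ms, params$between_person_sd_ms)
    b <- pmax(b, 1000)  # keep intercepts physically plausible
    red_idio <- rnorm(np, 0, params$training_reduction_sd_ms)
    phq_pre <- pmin(pmax(rnorm(np, params$phq9_pre_mean,
                               params$phq9_pre_sd), 0), 27)
    phq_change <- rnorm(np, params$phq9_effect_d * params$phq9_change_sd,
                        params$phq9_change_sd)
    pre_low <- runif(np) < params$adherence_pre_low_prob
    improve <- runif(np) < params$adherence_improve_prob
    worsen <- runif(np) < params$adherence_worsen_prob
    post_low <- ifelse(pre_low, !improve, worsen)
    data.frame(
      participant_id = ids, rt_intercept_ms = b,
      reduction_idiosyncratic_ms = red_idio,
      phq9_pre_latent = phq_pre, phq9_change_latent = phq_change,
      adherence_pre_low = pre_low, adherence_post_low = post_low,
      stringsAsFactors = FALSE
    )
  })

  inventories <- similarity <- NULL
  if ("inventories" %in% what) {
    inventories <- setNames(lapply(seq_len(np), function(i) {
      generate_inventory(ids[i], params$n_stimuli,
                         sub_seed(params$seed, i, stream = 2L))
    }), ids)
  }
  if ("similarity" %in% what) {
    similarity <- setNames(lapply(seq_len(np), function(i) {
      generate_similarity(inventories[[i]],
                          seed = sub_seed(params$seed, i, stream = 3L),
                          scale_bounds = params$similarity_scale,
                          noise_sd = params$similarity_noise_sd)
    }), ids)
  }

  session_logs <- NULL
  if ("trials" %in% what) {
    session_logs <- vector("list", 2L * np)
    for (i in seq_len(np)) {
      part <- classify_for_training(inventories[[i]])
      b_dev <- participants$rt_intercept_ms[i] - params$rt_baseline_mean_ms
      base_means <- participants$rt_intercept_ms[i] +
        params$pairing_offsets_ms
      reductions <- params$training_reduction_mean_ms +
        params$reduction_offsets_ms +
        params$reduction_baseline_coupling * b_dev +
        participants$reduction_idiosyncratic_ms[i]
      for (per in seq_along(PERIOD_LEVELS)) {
        period <- PERIOD_LEVELS[per]
        plan <- build_session_plan(
          part$probe_targets, part$distractors, constants,
          seed = sub_seed(params$seed, i, stream = 4L + per))
        means <- if (period == "baseline") base_means
                 else pmax(base_means - reductions, 400)
        lapse <- if (period == "baseline") params$lapse_rate_baseline
                 else params$lapse_rate_post
        session_logs[[2L * (i - 1L) + per]] <- simulate_session(
          plan, setNames(means, PAIRING_TYPES), params, lapse, constants,
          participant_id = ids[i], session_index = per,
          assessment_period = period,
          seed = sub_seed(params$seed, i, stream = 6L + per))
      }
    }
  }

  surveys <- NULL
  if ("surveys" %in% what) {
    rows <- with_seed(sub_seed(params$seed, 0L, stream = 9L), {
      do.call(rbind, lapply(seq_len(np), function(i) {
        pre_total <- as.integer(round(participants$phq9_pre_latent[i]))
        post_total <- as.integer(round(min(max(
          participants$phq9_pre_latent[i] -
            participants$phq9_change_latent[i], 0), 27)))
        do.call(rbind, lapply(PERIOD_LEVELS, function(period) {
          total <- if (period == "baseline") pre_total else post_total
          low <- if (period == "baseline") participants$adherence_pre_low[i]
                 else participants$adherence_post_low[i]
          items <- split_total(total, 9L, 0L, 3L)
          data.frame(
            participant_id = ids[i], period = period,
            phq9_total = sum(items),
            phq9_items = I(list(items)),
            vas_category = if (low) 3L else 4L,
            pclc_total = as.integer(round(min(max(
              17 + (total / 27) * 40 + rnorm(1, 0, 6), 17), 85))),
            mms_anxiety_total = as.integer(rbinom(1, 9, min(
              0.25 + 0.45 * total / 27, 1))),
            stringsAsFactors = FALSE
          )
        }))
      }))
    })
    surveys <- rows
  }

  structure(
    list(params = params, participants = participants,
         inventories = inventories, similarity = similarity,
         session_logs = session_logs, surveys = surveys),
    class = "synthetic_cohort"
  )
}

#' Monte-Carlo parameter-recovery study over full analysis pipelines
#'
#' Repeatedly generates cohorts, runs the complete analysis pipeline on
#' each (correct-only filtering, 1.5 SD trimming, pairing-type means and
#' paired tests for RT; PHQ-9 paired t and Cohen's d; adherence 2x2
#' chi-square and phi), and compares the recovered estimates with the
#' generating values.
#'
#' @param params a [cohort_params()]; `params$seed` is re-derived per
#'   replicate from `seed`.
#' @param n_reps number of replicate cohorts (capped at 200, the intended
#'   desk scale).
#' @param seed master seed for the replicate stream.
#' @return list of class `recovery_report` with `replicates` (one row per
#'   replicate: recovered PHQ-9 d, per-pairing RT reductions and d, phi)
#'   and `summary` (per quantity: generating value, mean recovered
#'   estimate, bias, Monte-Carlo 95% CI of the mean).
#' @export
parameter_recovery_suite <- function(params = cohort_params(),
                                     n_reps = 200L, seed = 1L) {
  dp_assert(is_count(n_reps) && n_reps <= 200L,
            "n_reps must be a count <= 200")
  reps <- lapply(seq_len(n_reps), function(r) {
    p <- params
    p$seed <- sub_seed(seed, r, stream = 31L)
    coh <- generate_cohort(p, what = c("trials", "surveys"))
    obs <- as_rt_observations(coh$session_logs)
    pmt <- pairing_means(suppressWarnings(
      trim_outliers(filter_correct(obs))))
    phq <- coh$surveys
    pre <- phq$phq9_total[phq$period == "baseline"]
    post <- phq$phq9_total[phq$period == "posttraining"]
    tt <- paired_t(pre, post)
    adh <- categorical_change_test(
      adherence_category(phq$vas_category[phq$period == "baseline"]),
      adherence_category(phq$vas_category[phq$period == "posttraining"]))
    out <- data.frame(rep = r,
                      phq9_d = cohen_d_paired(tt$t, tt$n),
                      phi = adh$phi)
    for (ty in PAIRING_TYPES) {
      row <- pmt[pmt$pairing_type == ty, ]
      out[[paste0("delta_", gsub("-", "_", ty))]] <- row$delta_ms
      out[[paste0("d_", gsub("-", "_", ty))]] <- row$cohen_d
    }
    out
  })
  replicates <- do.call(rbind, reps)

  mc_ci <- function(x) {
    x <- x[is.finite(x)]
    m <- mean(x)
    half <- qt(0.975, length(x) - 1L) * sd(x) / sqrt(length(x))
    c(mean = m, lo = m - half, hi = m + half)
  }
  gen <- c(phq9_d = params$phq9_effect_d,
           setNames(params$training_reduction_mean_ms +
                      unname(params$reduction_offsets_ms),
                    paste0("delta_", gsub("-", "_", PAIRING_TYPES))))
  summary <- do.call(rbind, lapply(names(gen), function(q) {
    ci <- mc_ci(replicates[[q]])
    data.frame(quantity = q, generating = unname(gen[q]),
               mean_recovered = ci["mean"], bias = ci["mean"] - gen[q],
               ci_lo = ci["lo"], ci_hi = ci["hi"],
               stringsAsFactors = FALSE, row.names = NULL)
  }))
  structure(list(replicates = replicates, summary = summary,
                 n_reps = n_reps, seed = as.integer(seed)),
            class = "recovery_report")
}
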