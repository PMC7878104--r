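# Reaction-time preprocessing: correct-only filtering, per-participant
# +/- k SD trimming, and pairing-type by assessment-period summaries.

#' Flatten session logs into reaction-time observations
#'
#' @param logs a `session_log` or list of them (typically the baseline and
#'   posttraining assessment administrations).
#' @return data.frame with columns `participant_id`, `assessment_period`,
#'   `pairing_type`, `rt_ms`, `correct`; timeout trials (no response) are
#'   retained with `rt_ms = NA` and `correct = FALSE` so that accuracy
#'   tables see them, while RT summaries never do.
#' @export
as_rt_observations <- function(logs) {
  if (inherits(logs, "session_log")) logs <- list(logs)
  dp_assert(length(logs) >= 1L &&
              all(vapply(logs, inherits, logical(1), "session_log")),
            "logs must be session_log objects")
  do.call(rbind, lapply(logs, function(l) {
    data.frame(
      participant_id = l$participant_id,
      assessment_period = l$assessment_period,
      pairing_type = l$trials$pairing_type,
      rt_ms = l$trials$rt_ms,
      correct = l$trials$correct,
      stringsAsFactors = FALSE
    )
  }))
}

validate_observations <- function(obs) {
  dp_assert(is.data.frame(obs), "observations must be a data.frame")
  needed <- c("participant_id", "assessment_period", "pairing_type",
              "rt_ms", "correct")
  dp_assert(all(needed %in% names(obs)),
            "observations need columns: %s", paste(needed, collapse = ", "))
  dp_assert(all(obs$rt_ms > 0, na.rm = TRUE), "rt_ms must be positive")
  obs
}

#' Keep reaction times from correct responses only
#'
#' RT analyses use correct responses only; incorrect responses and
#' timeouts are dropped before any trimming or averaging.
#'
#' @param obs observation data.frame (see [as_rt_observations()]).
#' @return the subset of `obs` with `correct == TRUE` and a recorded RT.
#' @export
filter_correct <- function(obs) {
  obs <- validate_observations(obs)
  obs[obs$correct & !is.na(obs$rt_ms), , drop = FALSE]
}

#' Trim reaction-time outliers per participant
#'
#' Eliminates reaction times more than `k` standard deviations above or
#' below a participant's mean response time.  The reference mean and SD
#' are computed once per participant within each assessment period,
#' pooled across pairing types (a single pass; no iterative re-trimming).
#' A participant-period group with fewer than two observations, or with
#' zero variance, is retained untrimmed (with a warning in the former
#' case).
#'
#' @param obs correct-only observation data.frame.
#' @param k trim width in SD units (default 1.5).
#' @return the retained subset of `obs`; the number of removed rows is
#'   attached as attribute `n_removed`.
#' @export
trim_outliers <- function(obs, k = 1.5) {
  obs <- validate_observations(obs)
  dp_assert(is.numeric(k) && length(k) == 1L && k > 0,
            "k must be a positive scalar")
  dp_assert(!anyNA(obs$rt_ms), "trim_outliers expects correct-only data")
  grp <- interaction(obs$participant_id, obs$assessment_period, drop = TRUE)
  keep <- logical(nrow(obs))
  small <- character(0)
  for (g in levels(grp)) {
    idx <- which(grp == g)
    x <- obs$rt_ms[idx]
    if (length(x) < 2L) {
      keep[idx] <- TRUE
      small <- c(small, g)
      next
    }
    m <- mean(x)
    s <- sd(x)
    keep[idx] <- if (s == 0) TRUE else x >= m - k * s & x <= m + k * s
  }
  if (length(small)) {
    warning(sprintf(
      "retained untrimmed (fewer than 2 observations): %s",
      paste(small, collapse = ", ")), call. = FALSE)
  }
  out <- obs[keep, , drop = FALSE]
  attr(out, "n_removed") <- sum(!keep)
  out
}

#' Pairing-type by assessment-period mean reaction-time table
#'
#' Participant-level mean RTs are computed per pairing type and period;
#' cohort means and SDs are then taken over participants (so each
#' participant contributes equally and the SD reflects between-person
#' dispersion), and baseline vs posttraining is compared by a two-sided
#' paired t test on the participant means, with the paired Cohen's d
#' (`|t|/sqrt(n)`).  Participants missing a period are excluded pairwise
#' from that row's test.
#'
#' @param obs trimmed, correct-only observations.
#' @return data.frame of class `pairing_means_table`, one row per pairing
#'   type in canonical order, with columns `pairing_type`, `n`,
#'   `baseline_mean`, `baseline_sd`, `posttraining_mean`,
#'   `posttraining_sd`, `delta_ms`, `t`, `df`, `p`, `cohen_d`.
#' @export
pairing_means <- function(obs) {
  obs <- validate_observations(obs)
  dp_assert(all(obs$pairing_type %in% PAIRING_TYPES),
            "unknown pairing type(s): %s",
            paste(setdiff(unique(obs$pairing_type), PAIRING_TYPES),
                  collapse = ", "))
  dp_assert(all(obs$assessment_period %in% PERIOD_LEVELS),
            "assessment_period must be baseline or posttraining")
  pm <- aggregate(rt_ms ~ participant_id + assessment_period + pairing_type,
                  data = obs, FUN = mean)
  rows <- lapply(PAIRING_TYPES, function(type) {
    sub <- pm[pm$pairing_type == type, , drop = FALSE]
    base <- sub[sub$assessment_period == "baseline", ]
    post <- sub[sub$assessment_period == "posttraining", ]
    both <- intersect(base$participant_id, post$participant_id)
    b <- base$rt_ms[match(both, base$participant_id)]
    p <- post$rt_ms[match(both, post$participant_id)]
    tt <- if (length(both) >= 2L) paired_t(b, p) else
      list(t = NA_real_, df = NA_real_, p = NA_real_)
    data.frame(
      pairing_type = type,
      n = length(both),
      baseline_mean = if (nrow(base)) mean(base$rt_ms) else NA_real_,
      baseline_sd = if (nrow(base) > 1L) sd(base$rt_ms) else NA_real_,
      posttraining_mean = if (nrow(post)) mean(post$rt_ms) else NA_real_,
      posttraining_sd = if (nrow(post) > 1L) sd(post$rt_ms) else NA_real_,
      t = tt$t, df = tt$df, p = tt$p,
      cohen_d = if (is.na(tt$t)) NA_real_ else
        cohen_d_paired(tt$t, length(both)),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  out$delta_ms <- out$baseline_mean - out$posttraining_mean
  out <- out[, c("pairing_type", "n", "baseline_mean", "baseline_sd",
                 "posttraining_mean", "posttraining_sd", "delta_ms",
                 "t", "df", "p", "cohen_d")]
  class(out) <- c("pairing_means_table", "data.frame")
  out
}

#' Accuracy by pairing type and assessment period
#'
#' Uses the untrimmed observations, including incorrect and timeout
#' trials: accuracy is correct/total within each pairing-by-period cell.
#'
#' @param obs observation data.frame including incorrect trials.
#' @return data.frame with `pairing_type`, `assessment_period`,
#'   `n_trials`, `n_correct`, `accuracy` (NA for empty cells).
#' @export
accuracy_table <- function(obs) {
  obs <- validate_observations(obs)
  grid <- expand.grid(pairing_type = PAIRING_TYPES,
                      assessment_period = PERIOD_LEVELS,
                      stringsAsFactors = FALSE)
  grid$n_trials <- NA_integer_
  grid$n_correct <- NA_integer_
  grid$accuracy <- NA_real_
  for (i in seq_len(nrow(grid))) {
    sel <- obs$pairing_type == grid$pairing_type[i] &
      obs$assessment_period == grid$assessment_period[i]
    n <- sum(sel)
    grid$n_trials[i] <- n
    grid$n_correct[i] <- sum(obs$correct[sel])
    grid$accuracy[i] <- if (n > 0) grid$n_correct[i] / n else NA_real_
  }
  grid
}
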