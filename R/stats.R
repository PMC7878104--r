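# Pre/post outcome statistics: paired t, effect-size conventions, paired
# categorical change, and the assembled outcome report.

#' Two-sided paired t test
#'
#' Wraps [stats::t.test()] on the paired differences, with explicit
#' handling of the degenerate zero-variance case that a small pre/post
#' cohort can produce: identical pre and post vectors give `t = 0`,
#' `p = 1`; constant nonzero differences give an infinite `t`; both are
#' flagged `degenerate`.
#'
#' @param pre,post equal-length numeric vectors, pairs complete, `n >= 2`.
#' @return list with `t`, `df`, `p`, `mean_diff` (pre - post), `sd_diff`,
#'   `n`, `degenerate`.
#' @export
paired_t <- function(pre, post) {
  dp_assert(is.numeric(pre) && is.numeric(post), "inputs must be numeric")
  dp_assert(length(pre) == length(post),
            "pre and post must be paired (equal length)")
  dp_assert(!anyNA(pre) && !anyNA(post), "paired vectors must be complete")
  n <- length(pre)
  dp_assert(n >= 2L, "need at least 2 pairs")
  d <- pre - post
  if (sd(d) == 0) {
    t_stat <- if (mean(d) == 0) 0 else sign(mean(d)) * Inf
    return(list(t = t_stat, df = n - 1L, p = if (t_stat == 0) 1 else 0,
                mean_diff = mean(d), sd_diff = 0, n = n, degenerate = TRUE))
  }
  tt <- t.test(pre, post, paired = TRUE, alternative = "two.sided")
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p = tt$p.value, mean_diff = mean(d), sd_diff = sd(d), n = n,
       degenerate = FALSE)
}

#' Paired-design Cohen's d from a t statistic
#'
#' Uses the convention `d = |t| / sqrt(n)` for pre/post designs, i.e. the
#' standardized mean change (mean difference over the SD of the
#' differences).  The magnitude is reported; the direction of change is
#' carried by the means themselves.
#'
#' @param t paired t statistic.
#' @param n number of pairs (participants), `n >= 1`.
#' @return non-negative scalar d.
#' @seealso [cohen_d_change()] for the equivalent computation from raw
#'   paired vectors.
#' @export
cohen_d_paired <- function(t, n) {
  dp_assert(is.numeric(t) && length(t) == 1L, "t must be a scalar")
  dp_assert(is_count(n), "n must be a positive integer")
  abs(t) / sqrt(n)
}

#' Standardized mean change from raw paired vectors
#'
#' Secondary convention: `mean(pre - post) / sd(pre - post)`, identical in
#' magnitude to [cohen_d_paired()] applied to the paired t statistic.
#'
#' @param pre,post equal-length numeric vectors.
#' @return signed scalar d (positive when values decreased).
#' @export
cohen_d_change <- function(pre, post) {
  dp_assert(length(pre) == length(post) && length(pre) >= 2L,
            "need >= 2 complete pairs")
  d <- pre - post
  dp_assert(sd(d) > 0, "zero-variance differences; d undefined")
  mean(d) / sd(d)
}

#' Phi effect size for a 2x2 categorical association
#'
#' `phi = sqrt(chi2 / n)` where `n` is the number of participants.
#'
#' @param chi2 non-negative chi-square statistic.
#' @param n number of participants, `n >= 1`.
#' @return non-negative scalar phi.
#' @export
phi_effect <- function(chi2, n) {
  dp_assert(is.numeric(chi2) && length(chi2) == 1L && is.finite(chi2),
            "chi2 must be a finite scalar")
  dp_assert(chi2 >= 0, "chi2 must be non-negative")
  dp_assert(is_count(n), "n must be a positive integer")
  sqrt(chi2 / n)
}

#' Percent reduction from a baseline mean
#'
#' `100 * (pre - post) / pre`; reported rounded to an integer percent in
#' the formatted tables.
#'
#' @param pre_mean baseline mean, strictly positive.
#' @param post_mean posttraining mean.
#' @return percent reduction (positive when the mean decreased).
#' @export
percent_reduction <- function(pre_mean, post_mean) {
  dp_assert(is.numeric(pre_mean) && length(pre_mean) == 1L && pre_mean > 0,
            "pre_mean must be a positive scalar")
  100 * (pre_mean - post_mean) / pre_mean
}

#' Chi-square test of paired categorical change
#'
#' Builds the pre-by-post 2x2 contingency table over participants (each
#' participant contributes one cell) and computes the standard Pearson
#' chi-square on it, without continuity correction.  `n` is the number of
#' participants, so [phi_effect()] applied to the result uses participant
#' counts.
#'
#' @param pre_categories,post_categories paired category labels, one pair
#'   per participant, with the same two levels.
#' @return list with `table` (2x2 pre x post counts), `chi2`, `df`, `p`,
#'   `n`, `phi`, and `degenerate` (TRUE when a margin is empty and the
#'   statistic is undefined).
#' @export
categorical_change_test <- function(pre_categories, post_categories) {
  dp_assert(length(pre_categories) == length(post_categories),
            "pre and post categories must be paired")
  n <- length(pre_categories)
  dp_assert(n >= 1L, "need at least one participant")
  dp_assert(!anyNA(pre_categories) && !anyNA(post_categories),
            "category labels must be complete")
  levs <- sort(unique(c(as.character(pre_categories),
                        as.character(post_categories))))
  dp_assert(length(levs) <= 2L, "expected two category levels, got %d",
            length(levs))
  pre <- factor(pre_categories, levels = levs)
  post <- factor(post_categories, levels = levs)
  tab <- table(pre = pre, post = post)
  degenerate <- length(levs) < 2L || any(rowSums(tab) == 0) ||
    any(colSums(tab) == 0)
  if (degenerate) {
    return(list(table = tab, chi2 = NA_real_, df = NA_real_, p = NA_real_,
                n = n, phi = NA_real_, degenerate = TRUE))
  }
  ct <- suppressWarnings(chisq.test(tab, correct = FALSE))
  chi2 <- unname(ct$statistic)
  list(table = tab, chi2 = chi2, df = unname(ct$parameter), p = ct$p.value,
       n = n, phi = phi_effect(chi2, n), degenerate = FALSE)
}

#' Assemble the pre/post outcome report
#'
#' Combines adherence categorization (paired chi-square and phi) with
#' PHQ-9 change statistics (paired t, Cohen's d, percent reduction) and
#' the severity-band distribution at each period.
#'
#' @param scored data.frame with one row per participant per period:
#'   columns `participant_id`, `period`, `phq9_total`, `vas_category`.
#'   Only participants observed at both periods enter the paired
#'   statistics.
#' @return list of class `outcome_report`.
#' @export
outcome_report <- function(scored) {
  dp_assert(is.data.frame(scored) &&
              all(c("participant_id", "period", "phq9_total",
                    "vas_category") %in% names(scored)),
            paste("scored must have columns participant_id, period,",
                  "phq9_total, vas_category"))
  dp_assert(all(scored$period %in% PERIOD_LEVELS), "invalid period labels")
  base <- scored[scored$period == "baseline", ]
  post <- scored[scored$period == "posttraining", ]
  both <- intersect(base$participant_id, post$participant_id)
  dropped <- setdiff(unique(scored$participant_id), both)
  dp_assert(length(both) >= 2L,
            "need at least 2 participants with both periods")
  bi <- match(both, base$participant_id)
  pi <- match(both, post$participant_id)

  adher <- categorical_change_test(
    adherence_category(base$vas_category[bi]),
    adherence_category(post$vas_category[pi])
  )
  phq_pre <- base$phq9_total[bi]
  phq_post <- post$phq9_total[pi]
  tt <- paired_t(phq_pre, phq_post)
  bands <- lapply(list(baseline = phq_pre, posttraining = phq_post),
                  function(x) table(phq9_band(x)))
  structure(
    list(
      n = length(both),
      excluded_participants = dropped,
      adherence = adher,
      phq9 = list(
        pre_mean = mean(phq_pre), pre_sd = sd(phq_pre),
        post_mean = mean(phq_post), post_sd = sd(phq_post),
        t = tt$t, df = tt$df, p = tt$p, degenerate = tt$degenerate,
        cohen_d = if (is.finite(tt$t)) cohen_d_paired(tt$t, tt$n)
                  else NA_real_,
        percent_reduction = if (mean(phq_pre) > 0)
          percent_reduction(mean(phq_pre), mean(phq_post)) else NA_real_
      ),
      severity_bands = bands
    ),
    class = "outcome_report"
  )
}

#' @export
print.outcome_report <- function(x, ...) {
  cat(sprintf("Outcome report (n = %d paired participants)\n", x$n))
  cat(sprintf(
    "Adherence low -> moderate/high shift: chi2 = %s, phi = %s\n",
    fmt_fixed(x$adherence$chi2, 1), fmt_fixed(x$adherence$phi, 2)))
  cat(sprintf(
    "PHQ-9: %s (%s) -> %s (%s); t(%s) = %s, d = %s, reduction %s%%\n",
    fmt_fixed(x$phq9$pre_mean, 1), fmt_fixed(x$phq9$pre_sd, 1),
    fmt_fixed(x$phq9$post_mean, 1), fmt_fixed(x$phq9$post_sd, 1),
    fmt_fixed(x$phq9$df, 0), fmt_fixed(x$phq9$t, 2),
    fmt_fixed(x$phq9$cohen_d, 2),
    fmt_fixed(x$phq9$percent_reduction, 0)))
  invisible(x)
}
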