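# Screening-instrument scoring.  These are screening scores with the
# instruments' published cut points, not diagnoses.

check_items <- function(items, n, lo, hi, label) {
  dp_assert(is.numeric(items), "%s items must be numeric", label)
  dp_assert(length(items) == n, "%s requires exactly %d items (got %d)",
            label, n, length(items))
  if (anyNA(items)) return(FALSE)  # missing items: flagged, never imputed
  dp_assert(all(items >= lo & items <= hi & items == floor(items)),
            "%s items must be integers in %d-%d", label, lo, hi)
  TRUE
}

#' Score the PHQ-9 depression screener
#'
#' Nine items scored 0-3; total 0-27.  Severity bands: minimal (<=4),
#' mild (5-9), moderate (10-14), moderately-severe (15-19), severe (>=20).
#' A total of 10 or greater flags the score as above the conventional
#' cutoff suggesting further evaluation for major depression.
#'
#' @param items numeric vector of 9 item responses in 0-3; any `NA` marks
#'   the battery incomplete and no score is produced.
#' @return list with `total`, `band`, `above_cutoff_10`, `complete`.
#' @export
phq9_score <- function(items) {
  complete <- check_items(items, 9L, 0L, 3L, "PHQ-9")
  if (!complete) {
    return(list(total = NA_integer_, band = NA_character_,
                above_cutoff_10 = NA, complete = FALSE))
  }
  total <- as.integer(sum(items))
  list(total = total, band = phq9_band(total),
       above_cutoff_10 = total >= 10L, complete = TRUE)
}

#' @rdname phq9_score
#' @param total integer PHQ-9 total in 0-27 (vectorized).
#' @export
phq9_band <- function(total) {
  dp_assert(all(total >= 0 & total <= 27, na.rm = TRUE),
            "PHQ-9 totals must lie in 0-27")
  cut(total, breaks = c(-1, 4, 9, 14, 19, 27),
      labels = c("minimal", "mild", "moderate", "moderately-severe",
                 "severe"))
}

#' Score the PCL-C trauma-symptom checklist
#'
#' Seventeen items on a 1-5 Likert scale; totals range 17-85.  Totals of
#' 30 or more are flagged as screening positive for further PTSD
#' evaluation in civilian populations.
#'
#' @param items numeric vector of 17 item responses in 1-5.
#' @return list with `total`, `screen_positive`, `complete`.
#' @export
pclc_score <- function(items) {
  complete <- check_items(items, 17L, 1L, 5L, "PCL-C")
  if (!complete) {
    return(list(total = NA_integer_, screen_positive = NA, complete = FALSE))
  }
  total <- as.integer(sum(items))
  list(total = total, screen_positive = total >= 30L, complete = TRUE)
}

#' Score the anxiety subset of the Modified Mini Screen
#'
#' Nine anxiety items; totals of 6 or greater indicate elevated anxiety.
#' Item coding is configurable because published administrations vary;
#' the default is dichotomous 0/1.
#'
#' @param items numeric vector of 9 item responses.
#' @param item_max maximum item value (default 1, dichotomous coding).
#' @return list with `total`, `elevated`, `complete`.
#' @export
mms_anxiety_score <- function(items, item_max = 1L) {
  complete <- check_items(items, 9L, 0L, item_max, "MMS anxiety")
  if (!complete) {
    return(list(total = NA_integer_, elevated = NA, complete = FALSE))
  }
  total <- as.integer(sum(items))
  list(total = total, elevated = total >= 6L, complete = TRUE)
}

#' Categorize visual-analogue-scale adherence bins
#'
#' The modified VAS asks for the percentage of doses taken in four bins
#' (1: 0-25%, 2: 25-50%, 3: 50-75%, 4: 75-100%).  Bins 1-3 (at or below
#' the 75% threshold) are "low" adherence; bin 4 is "moderate/high".
#'
#' @param vas_category integer vector of bins in 1-4.
#' @return character vector, `"low"` or `"moderate/high"`.
#' @export
adherence_category <- function(vas_category) {
  dp_assert(is.numeric(vas_category) && !anyNA(vas_category) &&
              all(vas_category %in% 1:4),
            "vas_category must be integers in 1-4")
  ifelse(vas_category <= 3, "low", "moderate/high")
}

#' Cronbach's alpha internal-consistency coefficient
#'
#' `alpha = k/(k-1) * (1 - sum(item variances) / var(total score))`.
#'
#' @param item_matrix numeric matrix, respondents in rows, items in
#'   columns; at least 2 items and 2 respondents.
#' @return scalar alpha; `NA` with a warning when the total-score variance
#'   is zero (alpha undefined).
#' @export
cronbach_alpha <- function(item_matrix) {
  m <- as.matrix(item_matrix)
  dp_assert(is.numeric(m) && ncol(m) >= 2L && nrow(m) >= 2L,
            "need a numeric matrix with >= 2 items and >= 2 respondents")
  dp_assert(!anyNA(m), "item matrix contains missing values")
  k <- ncol(m)
  total_var <- var(rowSums(m))
  if (total_var == 0) {
    warning("total-score variance is zero; alpha undefined", call. = FALSE)
    return(NA_real_)
  }
  k / (k - 1) * (1 - sum(apply(m, 2L, var)) / total_var)
}

#' Assemble one participant's survey battery at one assessment period
#'
#' Bundles raw item responses and derived scores.  Missing items leave the
#' affected score absent (flagged via `complete`), never imputed.
#'
#' @param participant_id identifier.
#' @param period `"baseline"` or `"posttraining"`.
#' @param phq9_items 9 items in 0-3.
#' @param pclc_items 17 items in 1-5 (optional).
#' @param mms_anxiety_items 9 items (optional).
#' @param vas_category adherence bin in 1-4.
#' @param stigma_items 6 logical items (optional).
#' @param csa_items 2 logical items (optional).
#' @return list of class `survey_battery` with raw items and a `scores`
#'   list.
#' @export
survey_battery <- function(participant_id, period, phq9_items, vas_category,
                           pclc_items = NULL, mms_anxiety_items = NULL,
                           stigma_items = NULL, csa_items = NULL) {
  dp_assert(period %in% PERIOD_LEVELS,
            "period must be one of: %s", paste(PERIOD_LEVELS, collapse = ", "))
  if (!is.null(stigma_items)) {
    dp_assert(length(stigma_items) == 6L && is.logical(stigma_items),
              "stigma_items must be 6 logical values")
  }
  if (!is.null(csa_items)) {
    dp_assert(length(csa_items) == 2L && is.logical(csa_items),
              "csa_items must be 2 logical values")
  }
  scores <- list(
    phq9 = phq9_score(phq9_items),
    adherence = adherence_category(vas_category),
    pclc = if (!is.null(pclc_items)) pclc_score(pclc_items),
    mms_anxiety = if (!is.null(mms_anxiety_items))
      mms_anxiety_score(mms_anxiety_items),
    stigma_any = if (!is.null(stigma_items)) any(stigma_items),
    csa_any = if (!is.null(csa_items)) any(csa_items)
  )
  structure(
    list(participant_id = participant_id, period = period,
         phq9_items = phq9_items, pclc_items = pclc_items,
         mms_anxiety_items = mms_anxiety_items, vas_category = vas_category,
         stigma_items = stigma_items, csa_items = csa_items,
         scores = scores),
    class = "survey_battery"
  )
}
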