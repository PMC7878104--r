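#' Construct and validate a stimulus inventory
#'
#' A stimulus inventory is one participant's set of elicited
#' treatment-related thoughts, each labelled with an emotional valence and
#' a treatment orientation.  These labels drive both probe-target
#' classification and trial construction.
#'
#' @param stimulus_id character vector of unique identifiers.
#' @param text short free-text thought content; non-empty and unique
#'   within the inventory.
#' @param valence one of `"positive"`, `"negative"`, `"neutral"` per
#'   stimulus.
#' @param orientation one of `"approach"`, `"avoidance"`, `"neutral"` per
#'   stimulus.
#' @return A `data.frame` of class `stimulus_inventory` with columns
#'   `stimulus_id`, `text`, `valence`, `orientation`.
#' @examples
#' inv <- stimulus_inventory(
#'   stimulus_id = c("s1", "s2"),
#'   text = c("taking my meds keeps me healthy", "pills remind me I am sick"),
#'   valence = c("positive", "negative"),
#'   orientation = c("approach", "avoidance")
#' )
#' @export
stimulus_inventory <- function(stimulus_id, text, valence, orientation) {
  inv <- data.frame(
    stimulus_id = as.character(stimulus_id),
    text = as.character(text),
    valence = as.character(valence),
    orientation = as.character(orientation),
    stringsAsFactors = FALSE
  )
  validate_inventory(inv)
}

#' @rdname stimulus_inventory
#' @param inv a data.frame with the four inventory columns.
#' @export
validate_inventory <- function(inv) {
  dp_assert(is.data.frame(inv), "inventory must be a data.frame")
  needed <- c("stimulus_id", "text", "valence", "orientation")
  missing_cols <- setdiff(needed, names(inv))
  dp_assert(length(missing_cols) == 0L,
            "inventory is missing columns: %s",
            paste(missing_cols, collapse = ", "))
  dp_assert(nrow(inv) >= 1L, "inventory is empty")
  dp_assert(!anyNA(inv[needed]), "inventory contains missing values")
  dp_assert(!any(duplicated(inv$stimulus_id)),
            "stimulus_id values must be unique")
  dp_assert(all(nzchar(trimws(inv$text))), "stimulus text must be non-empty")
  dp_assert(!any(duplicated(inv$text)),
            "stimulus text must be unique within an inventory")
  bad_v <- setdiff(unique(inv$valence), VALENCE_LEVELS)
  dp_assert(length(bad_v) == 0L, "invalid valence label(s): %s",
            paste(bad_v, collapse = ", "))
  bad_o <- setdiff(unique(inv$orientation), ORIENTATION_LEVELS)
  dp_assert(length(bad_o) == 0L, "invalid orientation label(s): %s",
            paste(bad_o, collapse = ", "))
  class(inv) <- c("stimulus_inventory", "data.frame")
  inv
}

#' Schedule every pairwise combination of stimuli in seeded random order
#'
#' During the individualized assessment, participants rate the similarity
#' of every unordered pair of their elicited thoughts, with pairs shown in
#' random order.  This generates that schedule reproducibly.
#'
#' @param stimulus_ids character vector of at least two distinct ids.
#' @param seed integer seed governing the presentation order.
#' @return A `data.frame` with columns `stimulus_a`, `stimulus_b`, one row
#'   per unordered pair (`choose(n, 2)` rows), in seed-determined order.
#' @export
pair_schedule <- function(stimulus_ids, seed) {
  ids <- as.character(stimulus_ids)
  dp_assert(!any(duplicated(ids)), "stimulus ids must be distinct")
  dp_assert(length(ids) >= 2L, "need at least 2 stimuli to form pairs")
  pairs <- t(combn(ids, 2L))
  ord <- with_seed(seed, sample.int(nrow(pairs)))
  data.frame(
    stimulus_a = pairs[ord, 1L],
    stimulus_b = pairs[ord, 2L],
    stringsAsFactors = FALSE
  )
}

#' Construct validated pairwise similarity ratings
#'
#' @param stimulus_ids ordered character vector of n stimulus identifiers.
#' @param ratings symmetric n x n numeric matrix of similarity values.
#' @param scale_bounds length-2 numeric `c(s_min, s_max)` rating-scale
#'   bounds; the diagonal must equal `s_max` (self-similarity is maximal).
#' @return An object of class `similarity_ratings`.
#' @export
similarity_ratings <- function(stimulus_ids, ratings,
                               scale_bounds = c(1, 9)) {
  ids <- as.character(stimulus_ids)
  dp_assert(is.matrix(ratings) && is.numeric(ratings),
            "ratings must be a numeric matrix")
  dimnames(ratings) <- NULL  # value symmetry is what matters, not labels
  n <- length(ids)
  dp_assert(nrow(ratings) == n && ncol(ratings) == n,
            "ratings must be %d x %d to match stimulus_ids", n, n)
  dp_assert(length(scale_bounds) == 2L && scale_bounds[1] < scale_bounds[2],
            "scale_bounds must be c(s_min, s_max) with s_min < s_max")
  dp_assert(all(is.finite(ratings)), "ratings must be finite")
  dp_assert(isTRUE(all.equal(ratings, t(ratings), tolerance = 1e-8)),
            "ratings matrix must be symmetric")
  dp_assert(all(ratings >= scale_bounds[1] - 1e-8) &&
              all(ratings <= scale_bounds[2] + 1e-8),
            "ratings must lie within scale bounds [%g, %g]",
            scale_bounds[1], scale_bounds[2])
  dp_assert(isTRUE(all.equal(unname(diag(ratings)),
                             rep(scale_bounds[2], n), tolerance = 1e-8)),
            "diagonal must equal s_max (self-similarity maximal)")
  dimnames(ratings) <- list(ids, ids)
  structure(
    list(stimulus_ids = ids, ratings = ratings,
         scale_bounds = as.numeric(scale_bounds)),
    class = "similarity_ratings"
  )
}

#' Convert similarity ratings to a dissimilarity matrix
#'
#' Applies the linear reversal `d_ij = s_max - s_ij`, the simplest monotone
#' transform from a bounded similarity scale to dissimilarities suitable
#' for multidimensional scaling.
#'
#' @param sr a [similarity_ratings()] object.
#' @return Symmetric non-negative numeric matrix with zero diagonal.
#' @export
to_dissimilarity <- function(sr) {
  dp_assert(inherits(sr, "similarity_ratings"),
            "input must be a similarity_ratings object")
  d <- sr$scale_bounds[2] - sr$ratings
  diag(d) <- 0
  # clamp tiny negatives from boundary tolerance
  d[d < 0] <- 0
  d
}

#' Partition a labelled inventory into probe targets and distractors
#'
#' Probe targets are the stimuli the training task teaches attention
#' toward: treatment approach-oriented (or orientation-neutral) thoughts
#' with a positive or neutral emotional tone.  Everything else — negative
#' valence or avoidance orientation — is a distractor that the probe never
#' replaces.  The cognitive map, when supplied, is attached as diagnostic
#' provenance; the elicited labels alone govern classification.
#'
#' @param stimuli a [stimulus_inventory()] (or conforming data.frame).
#' @param map optional [mds_embed()] result covering the same stimulus
#'   ids, retained as provenance.
#' @return A list of class `training_partition` with elements
#'   `probe_targets`, `distractors` (both inventory data.frames) and
#'   `map`.
#' @export
classify_for_training <- function(stimuli, map = NULL) {
  inv <- validate_inventory(stimuli)
  if (!is.null(map)) {
    dp_assert(inherits(map, "cognitive_map"), "map must be a cognitive_map")
    dp_assert(setequal(map$stimulus_ids, inv$stimulus_id),
              "map must cover exactly the inventory's stimulus ids")
  }
  is_target <- inv$orientation %in% c("approach", "neutral") &
    inv$valence %in% c("positive", "neutral")
  structure(
    list(
      probe_targets = inv[is_target, , drop = FALSE],
      distractors = inv[!is_target, , drop = FALSE],
      map = map
    ),
    class = "training_partition"
  )
}
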