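# JSON-lines serialization of session logs: one header record then one
# record per trial.  JSON-lines is streamable and append-safe while a
# session is in progress, and round-trips bit-exactly.

TRIAL_COLUMNS <- c("trial_index", "block", "pairing_type",
                   "left_stimulus_id", "right_stimulus_id", "probe_side",
                   "probe_onset_ms", "response_side", "rt_ms", "correct",
                   "feedback_emitted")

#' Write a session log as JSON lines
#'
#' @param log a `session_log` from [run_session()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_session_log <- function(log, path) {
  dp_assert(inherits(log, "session_log"), "log must be a session_log")
  header <- list(
    record = "header",
    participant_id = log$participant_id,
    session_index = log$session_index,
    assessment_period = log$assessment_period,
    seed = log$seed,
    complete = log$complete,
    constants = unclass(log$constants)
  )
  if (!is.null(log$incomplete_reason)) {
    header$incomplete_reason <- log$incomplete_reason
  }
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(jsonlite::toJSON(header, auto_unbox = TRUE, digits = NA,
                              null = "null"), con)
  tr <- log$trials
  for (i in seq_len(nrow(tr))) {
    rec <- c(list(record = "trial"),
             as.list(tr[i, TRIAL_COLUMNS, drop = FALSE]))
    writeLines(jsonlite::toJSON(rec, auto_unbox = TRUE, digits = NA,
                                na = "null"), con)
  }
  invisible(path)
}

#' Read one session log from a JSON-lines file
#'
#' Every line is schema-validated; malformed or out-of-schema lines are
#' reported with their line numbers rather than silently coerced.
#'
#' @param path path to a file written by [write_session_log()].
#' @return A `session_log` object.
#' @export
read_session_log <- function(path) {
  dp_assert(file.exists(path), "no such file: %s", path)
  lines <- readLines(path, warn = FALSE)
  dp_assert(length(lines) >= 1L, "empty session log: %s", path)
  parsed <- vector("list", length(lines))
  bad <- integer(0)
  for (i in seq_along(lines)) {
    rec <- tryCatch(jsonlite::fromJSON(lines[i]), error = function(e) NULL)
    if (is.null(rec) || is.null(rec$record) ||
        !rec$record %in% c("header", "trial")) {
      bad <- c(bad, i)
    } else {
      parsed[[i]] <- rec
    }
  }
  if (length(bad)) {
    dp_stop("malformed session-log line(s) in %s: %s", path,
            paste(bad, collapse = ", "), class = "dotprobe_schema_error")
  }
  header <- parsed[[1L]]
  dp_assert(identical(header$record, "header"),
            "first line of %s must be the header record", path)
  trial_recs <- parsed[-1L]
  not_trial <- which(vapply(trial_recs, function(r) r$record != "trial",
                            logical(1)))
  if (length(not_trial)) {
    dp_stop("unexpected non-trial record at line(s): %s",
            paste(not_trial + 1L, collapse = ", "),
            class = "dotprobe_schema_error")
  }
  schema_bad <- integer(0)
  rows <- lapply(seq_along(trial_recs), function(i) {
    r <- trial_recs[[i]]
    if (!all(TRIAL_COLUMNS %in% names(r))) {
      schema_bad <<- c(schema_bad, i + 1L)
      return(NULL)
    }
    data.frame(
      trial_index = as.integer(r$trial_index),
      block = as.integer(r$block),
      pairing_type = as.character(r$pairing_type),
      left_stimulus_id = as.character(r$left_stimulus_id),
      right_stimulus_id = as.character(r$right_stimulus_id),
      probe_side = as.character(r$probe_side),
      probe_onset_ms = as.numeric(r$probe_onset_ms),
      response_side = as.character(r$response_side),
      rt_ms = if (is.null(r$rt_ms)) NA_real_ else as.numeric(r$rt_ms),
      correct = as.logical(r$correct),
      feedback_emitted = as.logical(r$feedback_emitted),
      stringsAsFactors = FALSE
    )
  })
  if (length(schema_bad)) {
    dp_stop("session-log line(s) missing required fields: %s",
            paste(schema_bad, collapse = ", "),
            class = "dotprobe_schema_error")
  }
  trials <- if (length(rows)) do.call(rbind, rows) else
    as.data.frame(setNames(rep(list(logical(0)), length(TRIAL_COLUMNS)),
                           TRIAL_COLUMNS))
  constants <- do.call(protocol_constants,
                       header$constants[setdiff(names(header$constants),
                                                c("trials_per_session",
                                                  "total_target_sessions"))])
  structure(
    list(
      participant_id = header$participant_id,
      session_index = as.integer(header$session_index),
      assessment_period = header$assessment_period,
      seed = as.integer(header$seed %||% NA_integer_),
      constants = constants,
      trials = trials,
      complete = isTRUE(header$complete),
      incomplete_reason = header$incomplete_reason
    ),
    class = "session_log"
  )
}

#' Read all session logs beneath a path
#'
#' @param path a directory (all `*.jsonl` files, recursively) or a
#'   character vector of file paths.
#' @return list of `session_log` objects.
#' @export
read_session_logs <- function(path) {
  files <- if (length(path) == 1L && dir.exists(path)) {
    sort(list.files(path, pattern = "\\.jsonl$", full.names = TRUE,
                    recursive = TRUE))
  } else {
    path
  }
  dp_assert(length(files) >= 1L, "no session-log files found")
  lapply(files, read_session_log)
}
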