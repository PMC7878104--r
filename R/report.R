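# Tabular I/O and report rendering: inventory and similarity CSV readers,
# formatted results tables at publication precision (RT means to integer
# ms, effect sizes to 2 decimals, percentages to integers), and run
# manifests for reproducibility.

#' Read a stimulus inventory from CSV
#'
#' Expects columns `stimulus_id`, `text`, `valence`, `orientation`; the
#' result is fully validated, never silently coerced.
#'
#' @param path CSV file path.
#' @return a [stimulus_inventory()].
#' @export
read_inventory_csv <- function(path) {
  dp_assert(file.exists(path), "no such file: %s", path)
  df <- read.csv(path, stringsAsFactors = FALSE)
  validate_inventory(df)
}

#' @rdname read_inventory_csv
#' @param inv inventory to write.
#' @export
write_inventory_csv <- function(inv, path) {
  write.csv(as.data.frame(validate_inventory(inv)), path, row.names = FALSE)
  invisible(path)
}

#' Read similarity ratings from CSV (long or square dialect)
#'
#' Auto-detects the dialect from the header: a long-form file has columns
#' `stimulus_a`, `stimulus_b`, `rating` (one row per unordered pair; the
#' matrix is completed symmetrically and the diagonal set to `s_max`);
#' a square file has stimulus ids as its first column and one column per
#' stimulus.
#'
#' @param path CSV file path.
#' @param scale_bounds rating-scale bounds (default `c(1, 9)`).
#' @return a [similarity_ratings()] object.
#' @export
read_similarity_csv <- function(path, scale_bounds = c(1, 9)) {
  dp_assert(file.exists(path), "no such file: %s", path)
  df <- read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (all(c("stimulus_a", "stimulus_b", "rating") %in% names(df))) {
    ids <- sort(unique(c(df$stimulus_a, df$stimulus_b)))
    m <- matrix(NA_real_, length(ids), length(ids),
                dimnames = list(ids, ids))
    for (i in seq_len(nrow(df))) {
      m[df$stimulus_a[i], df$stimulus_b[i]] <- df$rating[i]
      m[df$stimulus_b[i], df$stimulus_a[i]] <- df$rating[i]
    }
    diag(m) <- scale_bounds[2]
    dp_assert(!anyNA(m), "long-form similarity file is missing pairs")
    similarity_ratings(ids, m, scale_bounds)
  } else {
    ids <- as.character(df[[1L]])
    m <- as.matrix(df[, -1L, drop = FALSE])
    dp_assert(identical(colnames(m), ids),
              "square similarity file columns must match its id rows")
    storage.mode(m) <- "double"
    similarity_ratings(ids, m, scale_bounds)
  }
}

#' Export a cognitive map as coordinates CSV plus JSON sidecar
#'
#' @param map a [mds_embed()] result.
#' @param path output CSV path; the sidecar (stress, seed, iterations) is
#'   written next to it with extension `.json`.
#' @return `path`, invisibly.
#' @export
write_cognitive_map <- function(map, path) {
  dp_assert(inherits(map, "cognitive_map"), "map must be a cognitive_map")
  df <- data.frame(stimulus_id = map$stimulus_ids,
                   dim1 = map$coordinates[, 1L],
                   dim2 = map$coordinates[, 2L])
  write.csv(df, path, row.names = FALSE)
  sidecar <- sub("\\.csv$", ".json", path)
  if (identical(sidecar, path)) sidecar <- paste0(path, ".json")
  jsonlite::write_json(
    list(stress = map$stress, n_iterations = map$n_iterations,
         seed = map$seed),
    sidecar, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Format the pairing-type reaction-time table for publication
#'
#' Renders a [pairing_means()] result in the conventional results layout:
#' "mean (SD)" strings with means and SDs to integer ms, the paired t to
#' 2 decimals, and Cohen's d to 2 decimals.
#'
#' @param pmt a `pairing_means_table`.
#' @return data.frame of formatted strings with columns `pairing`,
#'   `baseline`, `posttraining`, `reduction_ms`, `t`, `p`, `cohen_d`.
#' @export
format_pairing_table <- function(pmt) {
  dp_assert(inherits(pmt, "pairing_means_table"),
            "pmt must come from pairing_means()")
  data.frame(
    pairing = pmt$pairing_type,
    baseline = sprintf("%s (%s)", fmt_fixed(pmt$baseline_mean, 0),
                       fmt_fixed(pmt$baseline_sd, 0)),
    posttraining = sprintf("%s (%s)", fmt_fixed(pmt$posttraining_mean, 0),
                           fmt_fixed(pmt$posttraining_sd, 0)),
    reduction_ms = fmt_fixed(pmt$delta_ms, 0),
    t = fmt_fixed(pmt$t, 2),
    p = fmt_fixed(pmt$p, 3),
    cohen_d = fmt_fixed(pmt$cohen_d, 2),
    stringsAsFactors = FALSE
  )
}

#' Format the adherence and depressive-symptom outcome table
#'
#' Renders an [outcome_report()] as a long-format table: adherence
#' category counts with integer percentages, PHQ-9 "mean (SD)" to one
#' decimal with t/p, and severity-band counts per period.
#'
#' @param report an `outcome_report`.
#' @return data.frame of formatted strings with columns `characteristic`,
#'   `baseline`, `posttraining`, `statistic`, `p`.
#' @export
format_outcome_table <- function(report) {
  dp_assert(inherits(report, "outcome_report"),
            "report must come from outcome_report()")
  n <- report$n
  tab <- report$adherence$table
  pct <- function(k) sprintf("%d (%s)", k, fmt_fixed(100 * k / n, 0))
  rows <- list(
    data.frame(characteristic = "Adherence <=75% (low)",
               baseline = pct(sum(tab["low", ])),
               posttraining = pct(sum(tab[, "low"])),
               statistic = fmt_fixed(report$adherence$chi2, 1),
               p = fmt_fixed(report$adherence$p, 3)),
    data.frame(characteristic = "Adherence >75% (moderate/high)",
               baseline = pct(sum(tab["moderate/high", ])),
               posttraining = pct(sum(tab[, "moderate/high"])),
               statistic = "", p = ""),
    data.frame(characteristic = "Depressive symptoms, mean (SD)",
               baseline = sprintf("%s (%s)",
                                  fmt_fixed(report$phq9$pre_mean, 1),
                                  fmt_fixed(report$phq9$pre_sd, 1)),
               posttraining = sprintf("%s (%s)",
                                      fmt_fixed(report$phq9$post_mean, 1),
                                      fmt_fixed(report$phq9$post_sd, 1)),
               statistic = fmt_fixed(report$phq9$t, 2),
               p = fmt_fixed(report$phq9$p, 3))
  )
  bands <- levels(phq9_band(0L))
  for (b in bands) {
    rows[[length(rows) + 1L]] <- data.frame(
      characteristic = paste0("Severity: ", b),
      baseline = pct(as.integer(report$severity_bands$baseline[b])),
      posttraining = pct(as.integer(report$severity_bands$posttraining[b])),
      statistic = "", p = "")
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Render a formatted table as markdown lines
#'
#' @param df data.frame of character columns.
#' @return character vector of markdown table lines.
#' @export
render_markdown_table <- function(df) {
  dp_assert(is.data.frame(df) && nrow(df) > 0L, "need a non-empty table")
  cells <- vapply(df, as.character, character(nrow(df)))
  if (is.null(dim(cells))) cells <- matrix(cells, nrow = 1L)
  header <- paste0("| ", paste(names(df), collapse = " | "), " |")
  sep <- paste0("|", paste(rep("---", ncol(df)), collapse = "|"), "|")
  body <- apply(cells, 1L, function(r)
    paste0("| ", paste(r, collapse = " | "), " |"))
  c(header, sep, body)
}

#' Write a reproducibility manifest for a pipeline run
#'
#' Records the package version, seed, configuration and input/output
#' counts so a run can be reproduced bit-identically.
#'
#' @param path output JSON path.
#' @param seed integer seed used for the run.
#' @param config named list of configuration values.
#' @param counts named list of stage in/out counts (attrition audit).
#' @return `path`, invisibly.
#' @export
write_run_manifest <- function(path, seed, config = list(),
                               counts = list()) {
  jsonlite::write_json(
    list(package = "dotprobe",
         version = as.character(utils::packageVersion("dotprobe")),
         seed = as.integer(seed), config = config, counts = counts,
         timestamp = format(Sys.time(), tz = "UTC",
                            format = "%Y-%m-%dT%H:%M:%SZ")),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
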