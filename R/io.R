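# CSV readers/writers for the node schema and the markdown evaluation
# report. Dialect: comma-separated, UTF-8, "." decimal point, booleans
# serialized 0/1, empty cell = absent (defaults documented per column).

required_cols <- function() {
  c("node_id", "region", morpho_cols(), grade_cols())
}

parse_num <- function(x, col, allow_na = FALSE) {
  out <- suppressWarnings(as.numeric(x))
  bad <- is.na(out) & !(allow_na & (is.na(x) | x == ""))
  if (any(bad)) {
    stop(sprintf("read_nodes: unparseable value '%s' in column %s, row %d",
                 x[which(bad)[1]], col, which(bad)[1]))
  }
  out
}

parse_bool <- function(x, col) {
  if (is.null(x)) return(NULL)
  x[is.na(x) | x == ""] <- "0"
  if (!all(x %in% c("0", "1"))) {
    bad <- which(!(x %in% c("0", "1")))[1]
    stop(sprintf("read_nodes: boolean column %s must be 0/1, row %d has '%s'",
                 col, bad, x[bad]))
  }
  x == "1"
}

#' Read lymph-node records from CSV
#'
#' Parses the [node_schema()] CSV dialect. Absent boolean columns (and
#' empty boolean cells) default to `FALSE`; an empty `vascular_pattern`
#' means Doppler was not performed; empty `histopathology` / `cohort`
#' means unknown. A validation report ([validate_nodes()]) is attached as
#' the `"violations"` attribute — records are returned even when
#' inconsistent, so the caller decides.
#'
#' @param path Path to a CSV file with the exact schema header.
#' @return Data frame of node records with attribute `violations`.
#' @export
read_nodes <- function(path) {
  raw <- utils::read.csv(path, colClasses = "character",
                         stringsAsFactors = FALSE, check.names = FALSE)
  missing_req <- setdiff(required_cols(), names(raw))
  if (length(missing_req) > 0L) {
    stop("read_nodes: malformed header, missing required column(s): ",
         paste(missing_req, collapse = ", "))
  }
  unknown <- setdiff(names(raw), node_schema())
  if (length(unknown) > 0L) {
    warning("read_nodes: ignoring unknown column(s): ",
            paste(unknown, collapse = ", "))
  }
  n <- nrow(raw)
  out <- data.frame(node_id = raw$node_id, region = raw$region,
                    stringsAsFactors = FALSE)
  for (cc in morpho_cols()) out[[cc]] <- parse_num(raw[[cc]], cc)
  for (cc in grade_cols()) out[[cc]] <- parse_num(raw[[cc]], cc)
  out$vascular_pattern <- if ("vascular_pattern" %in% names(raw)) {
    parse_num(raw$vascular_pattern, "vascular_pattern", allow_na = TRUE)
  } else rep(NA_real_, n)
  for (cc in c(finding_cols(), clinical_cols())) {
    out[[cc]] <- if (cc %in% names(raw)) parse_bool(raw[[cc]], cc)
    else rep(FALSE, n)
  }
  for (cc in c("histopathology", "cohort")) {
    x <- if (cc %in% names(raw)) raw[[cc]] else rep(NA_character_, n)
    x[!is.na(x) & x == ""] <- NA_character_
    out[[cc]] <- x
  }
  out <- out[, node_schema()]
  attr(out, "violations") <- validate_nodes(out)
  out
}

#' Write lymph-node records to CSV
#'
#' Inverse of [read_nodes()]: booleans as 0/1, absent values as empty
#' cells, columns in canonical schema order.
#'
#' @param nodes Data frame in the [node_schema()] layout.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_nodes <- function(nodes, path) {
  out <- nodes[, node_schema()]
  for (cc in c(finding_cols(), clinical_cols())) {
    out[[cc]] <- as.integer(out[[cc]])
  }
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Classify and evaluate a cohort in one pass
#'
#' Convenience wrapper running [classify_nodes()] then the evaluation
#' stage against the `histopathology` column: confusion summary,
#' diagnostic metrics, per-category risk, and (when cohort tags are
#' present) cohort-stratified sensitivity.
#'
#' @param nodes Data frame in the [node_schema()] layout with truth labels.
#' @param config A [rule_config()].
#' @param scheme Binarization scheme, see [binarize()].
#' @param level Confidence level for all intervals.
#' @return Object of class `lnrads_evaluation`: list with `classified`,
#'   `confusion`, `metrics`, `risk`, `cohort_sens` (or NULL), `config`,
#'   `scheme`, `level`, `n`.
#' @export
evaluate_nodes <- function(nodes, config = rule_config(),
                           scheme = c("statistical", "management"),
                           level = 0.95) {
  scheme <- match.arg(scheme)
  cls <- classify_nodes(nodes, config)
  truth <- as.character(nodes$histopathology)
  if (any(is.na(truth))) {
    stop("evaluate_nodes: histopathology truth required for every record")
  }
  cm <- confusion_summary(cls$category, truth, scheme)
  cohorts <- as.character(nodes$cohort)
  cs <- if (any(!is.na(cohorts) & cohorts %in% cohorts_malignant())) {
    cohort_sensitivity(cls$category, truth, cohorts, scheme, level)
  } else NULL
  res <- list(classified = cls, confusion = cm,
              metrics = diagnostic_metrics(cm, level),
              risk = risk_by_group(cls$category, truth, level),
              cohort_sens = cs, config = config, scheme = scheme,
              level = level, n = nrow(nodes))
  class(res) <- "lnrads_evaluation"
  res
}

# Half-up rounding to integer percent, for report display only.
pct <- function(x) floor(100 * x + 0.5)

#' Write a markdown evaluation report
#'
#' Emits the per-category confusion table, the metric block with
#' confidence intervals (integer-percent display, half-up), per-category
#' malignancy risk, per-cohort sensitivity when available, and the full
#' rule configuration used (provenance).
#'
#' @param results An `lnrads_evaluation` from [evaluate_nodes()].
#' @param path Output path for the markdown report.
#' @param seed Optional seed to echo for provenance.
#' @return Invisibly, `path`.
#' @export
write_report <- function(results, path, seed = NULL) {
  ln <- character()
  add <- function(...) ln <<- c(ln, sprintf(...))
  add("# LN-RADS evaluation report")
  add("")
  if (results$n == 0L) {
    add("no records")
    writeLines(ln, path)
    return(invisible(path))
  }
  cm <- results$confusion
  add("## Category / outcome composition (%s scheme, n = %d)", cm$scheme,
      cm$n)
  add("")
  add("| Category | Benign | Malignant | Test |")
  add("|----------|--------|-----------|------|")
  for (i in seq_len(nrow(cm$per_category))) {
    p <- cm$per_category[i, ]
    add("| LN-RADS %s | %d | %d | %s |", p$category, p$n_benign,
        p$n_malignant, if (p$positive) "positive" else "negative")
  }
  add("")
  add("TP %d", cm$tp); add("FP %d", cm$fp)
  add("TN %d", cm$tn); add("FN %d", cm$fn)
  add("")
  add("## Diagnostic metrics (%.0f%% CIs)", 100 * results$level)
  add("")
  for (i in seq_len(nrow(results$metrics))) {
    m <- results$metrics[i, ]
    if (is.na(m$estimate)) {
      add("- %s: %s", m$metric, m$note)
    } else {
      add("- %s: %d%% (CI %d-%d%%) [%d/%d]", m$metric, pct(m$estimate),
          pct(m$lower), pct(m$upper), m$k, m$n)
    }
  }
  add("")
  add("## Malignancy risk by category")
  add("")
  for (i in seq_len(nrow(results$risk))) {
    r <- results$risk[i, ]
    add("- LN-RADS %s: %d%% (%d/%d, CI %d-%d%%)", r$group, pct(r$risk),
        r$n_malignant, r$n, pct(r$lower), pct(r$upper))
  }
  if (!is.null(results$cohort_sens)) {
    add("")
    add("## Sensitivity by neoplasm cohort")
    add("")
    for (i in seq_len(nrow(results$cohort_sens))) {
      s <- results$cohort_sens[i, ]
      add("- %s: %d%% (%d/%d, CI %d-%d%%)", s$cohort, pct(s$sensitivity),
          s$n_positive, s$n, pct(s$lower), pct(s$upper))
    }
  }
  add("")
  add("## Configuration")
  add("")
  for (nm in names(results$config)) {
    add("- %s: %s", nm, format(results$config[[nm]]))
  }
  add("- scheme: %s", results$scheme)
  add("- ci_level: %s", format(results$level))
  if (!is.null(seed)) add("- seed: %s", format(seed))
  writeLines(ln, path)
  invisible(path)
}
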