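# Per-feature discrimination analysis: empirical ROC curves, rank-based
# AUC with DeLong interval, and Youden-index-optimal cutoffs.

check_two_class <- function(values, truth) {
  truth <- as.character(truth)
  if (length(values) != length(truth)) {
    stop("values and truth differ in length")
  }
  keep <- !is.na(values) & !is.na(truth)
  values <- values[keep]; truth <- truth[keep]
  if (!all(truth %in% c("benign", "malignant"))) {
    stop("truth must be 'benign'/'malignant'")
  }
  if (any(!is.finite(values))) stop("values must be finite")
  if (length(unique(truth)) < 2L) {
    stop("single-class input: need at least one benign and one malignant")
  }
  list(values = values, malignant = truth == "malignant")
}

# Orient so that larger oriented score means more malignant.
orient <- function(values, direction) {
  if (direction == "higher_is_malignant") values else -values
}

#' Empirical ROC curve
#'
#' One operating point per distinct observed value (the candidate cutoffs)
#' plus the trivial endpoints (0,0) and (1,1). Positivity at threshold `t`
#' is `value >= t` for `higher_is_malignant` and `value <= t` for
#' `lower_is_malignant`; tied values share a point.
#'
#' @param values Numeric feature values.
#' @param truth Vector of `"benign"` / `"malignant"`.
#' @param direction `"higher_is_malignant"` or `"lower_is_malignant"`.
#' @return Data frame with columns `threshold`, `fpr`, `tpr`, ordered from
#'   (0,0) to (1,1); the endpoint thresholds are infinite.
#' @export
roc_points <- function(values, truth,
                       direction = c("higher_is_malignant",
                                     "lower_is_malignant")) {
  direction <- match.arg(direction)
  d <- check_two_class(values, truth)
  s <- orient(d$values, direction)
  thr <- sort(unique(s), decreasing = TRUE)
  n1 <- sum(d$malignant); n0 <- sum(!d$malignant)
  tpr <- vapply(thr, function(t) sum(s >= t & d$malignant) / n1, numeric(1))
  fpr <- vapply(thr, function(t) sum(s >= t & !d$malignant) / n0, numeric(1))
  out <- data.frame(threshold = c(Inf, thr, -Inf),
                    fpr = c(0, fpr, 1), tpr = c(0, tpr, 1))
  out <- out[!duplicated(out[, c("fpr", "tpr")]), , drop = FALSE]
  if (direction == "lower_is_malignant") out$threshold <- -out$threshold
  rownames(out) <- NULL
  out
}

#' Area under the ROC curve with DeLong confidence interval
#'
#' The point estimate is the rank-based concordance statistic (probability
#' that a random malignant node scores above a random benign node, ties
#' counted one half). The interval is the asymptotic one from the DeLong
#' covariance of the paired placement values, clipped to `[0, 1]`.
#'
#' @inheritParams roc_points
#' @param level Confidence level, default 0.95.
#' @return One-row data frame: `auc`, `se`, `lower`, `upper`.
#' @export
roc_auc <- function(values, truth,
                    direction = c("higher_is_malignant",
                                  "lower_is_malignant"),
                    level = 0.95) {
  direction <- match.arg(direction)
  d <- check_two_class(values, truth)
  s <- orient(d$values, direction)
  x <- s[d$malignant]   # cases
  y <- s[!d$malignant]  # controls
  n1 <- length(x); n0 <- length(y)
  r <- rank(c(x, y))
  auc <- (sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  # DeLong placements
  v10 <- vapply(x, function(xi) (sum(xi > y) + 0.5 * sum(xi == y)) / n0,
                numeric(1))
  v01 <- vapply(y, function(yj) (sum(x > yj) + 0.5 * sum(x == yj)) / n1,
                numeric(1))
  se <- sqrt(stats::var(v10) / n1 + stats::var(v01) / n0)
  z <- stats::qnorm(1 - (1 - level) / 2)
  data.frame(auc = auc, se = se,
             lower = max(0, auc - z * se), upper = min(1, auc + z * se))
}

#' Youden-index-optimal cutoff with its metric panel
#'
#' Scans every distinct observed value as a candidate cutoff, maximizes
#' Youden's J = sensitivity + specificity - 1, and reports the full metric
#' panel at the winning cutoff together with the feature's AUC. Ties in J
#' are broken toward the smallest threshold under `higher_is_malignant`
#' (largest under `lower_is_malignant`), i.e. toward the more sensitive
#' operating point.
#'
#' @inheritParams roc_auc
#' @param feature_name Label carried into the result row.
#' @return One-row data frame: `feature`, `direction`, `n_benign`,
#'   `n_malignant`, `threshold`, `youden_j`, `sensitivity`, `specificity`,
#'   `accuracy`, `ppv`, `npv`, `auc`, `auc_lower`, `auc_upper`.
#' @export
youden_optimal <- function(values, truth,
                           direction = c("higher_is_malignant",
                                         "lower_is_malignant"),
                           feature_name = "feature", level = 0.95) {
  direction <- match.arg(direction)
  d <- check_two_class(values, truth)
  s <- orient(d$values, direction)
  n1 <- sum(d$malignant); n0 <- sum(!d$malignant)
  cand <- sort(unique(s), decreasing = TRUE)  # descending oriented cutoffs
  sens <- vapply(cand, function(t) sum(s >= t & d$malignant) / n1, numeric(1))
  spec <- vapply(cand, function(t) sum(s < t & !d$malignant) / n0, numeric(1))
  j <- sens + spec - 1
  # last index among the maxima = smallest oriented threshold
  best <- max(which(j == max(j)))
  thr <- if (direction == "lower_is_malignant") -cand[best] else cand[best]
  tp <- sens[best] * n1; tn <- spec[best] * n0
  fp <- n0 - tn; fn <- n1 - tp
  a <- roc_auc(d$values, ifelse(d$malignant, "malignant", "benign"),
               direction, level)
  data.frame(feature = feature_name, direction = direction,
             n_benign = n0, n_malignant = n1,
             threshold = thr, youden_j = j[best],
             sensitivity = sens[best], specificity = spec[best],
             accuracy = (tp + tn) / (n0 + n1),
             ppv = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
             npv = if (tn + fn > 0) tn / (tn + fn) else NA_real_,
             auc = a$auc, auc_lower = a$lower, auc_upper = a$upper)
}

#' Per-feature discrimination panel
#'
#' Runs [youden_optimal()] for each continuous node feature with its
#' field-standard direction: long axis, short axis, cortical thickness and
#' the S/L roundness ratio are malignant when high; the medulla fraction
#' MTD/(MTD+CTD) is malignant when low. The vascular pattern is analysed
#' only over nodes with a Doppler study.
#'
#' @param nodes Data frame in the [node_schema()] layout with a
#'   `histopathology` column.
#' @param level Confidence level for the AUC intervals.
#' @return Data frame with one [youden_optimal()] row per feature.
#' @export
feature_panel <- function(nodes, level = 0.95) {
  truth <- as.character(nodes$histopathology)
  if (all(is.na(truth))) stop("feature_panel: records carry no truth labels")
  nodes <- add_ratios(nodes)
  specs <- list(
    list("lad_mm", "LAD", "higher_is_malignant"),
    list("sad_mm", "SAD", "higher_is_malignant"),
    list("s_over_l", "S/L ratio", "higher_is_malignant"),
    list("ctd_mm", "CTD", "higher_is_malignant"),
    list("medulla_fraction", "MTD/(MTD+CTD) ratio", "lower_is_malignant"),
    list("vascular_pattern", "Vascular pattern", "higher_is_malignant"))
  rows <- lapply(specs, function(sp) {
    youden_optimal(nodes[[sp[[1]]]], truth, sp[[3]], sp[[2]], level)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
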