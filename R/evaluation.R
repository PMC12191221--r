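# Comparison of assigned categories against histopathology truth:
# confusion summaries, diagnostic metrics with Wilson intervals, per-group
# malignancy risk, and cohort-stratified sensitivity.

#' Binomial proportion confidence interval
#'
#' Wilson score interval (default) or Clopper-Pearson exact interval.
#' The Wilson interval always contains the point estimate and its bounds
#' are clipped to `[0, 1]`.
#'
#' @param k Number of successes (vectorised).
#' @param n Number of trials (vectorised).
#' @param level Confidence level, default 0.95.
#' @param method `"wilson"` or `"clopper-pearson"`.
#' @return Data frame with columns `lower`, `upper`.
#' @examples
#' proportion_ci(346, 389)  # rounds to the 85--92% interval
#' @export
proportion_ci <- function(k, n, level = 0.95,
                          method = c("wilson", "clopper-pearson")) {
  method <- match.arg(method)
  if (any(n <= 0)) stop("proportion_ci: n must be positive")
  if (any(k < 0 | k > n)) stop("proportion_ci: need 0 <= k <= n")
  if (method == "clopper-pearson") {
    a <- 1 - level
    lower <- ifelse(k == 0, 0, stats::qbeta(a / 2, k, n - k + 1))
    upper <- ifelse(k == n, 1, stats::qbeta(1 - a / 2, k + 1, n - k))
    return(data.frame(lower = lower, upper = upper))
  }
  z <- stats::qnorm(1 - (1 - level) / 2)
  p <- k / n
  denom <- 1 + z^2 / n
  centre <- (p + z^2 / (2 * n)) / denom
  half <- z / denom * sqrt(p * (1 - p) / n + z^2 / (4 * n^2))
  data.frame(lower = pmax(0, centre - half), upper = pmin(1, centre + half))
}

#' Per-category confusion summary under a binarization scheme
#'
#' Tallies benign/malignant histopathology per LN-RADS category and
#' collapses the table to TP/FP/TN/FN counts under the chosen scheme
#' (statistical: 4b-5 positive; management: 4a-5 positive). Malignant
#' nodes in positive categories are true positives; benign nodes there are
#' false positives, and symmetrically on the negative side.
#'
#' @param categories Vector coercible by [lnrads_factor()].
#' @param truth Vector of `"benign"` / `"malignant"`, same length.
#' @param scheme `"statistical"` or `"management"`.
#' @return Object of class `lnrads_confusion`: list with `per_category`
#'   (data frame: category, n_benign, n_malignant, positive), `scheme`,
#'   `tp`, `fp`, `tn`, `fn`, `n`.
#' @export
confusion_summary <- function(categories, truth,
                              scheme = c("statistical", "management")) {
  scheme <- match.arg(scheme)
  cat <- lnrads_factor(categories)
  truth <- as.character(truth)
  if (length(cat) != length(truth)) {
    stop("confusion_summary: categories and truth differ in length")
  }
  if (any(is.na(truth)) || !all(truth %in% c("benign", "malignant"))) {
    stop("confusion_summary: truth must be 'benign'/'malignant' for every record")
  }
  tab <- table(category = cat, truth = factor(truth,
                                              levels = c("benign", "malignant")))
  per <- data.frame(category = lnrads_levels(),
                    n_benign = as.integer(tab[, "benign"]),
                    n_malignant = as.integer(tab[, "malignant"]))
  per$positive <- binarize(per$category, scheme) == "positive"
  res <- list(per_category = per, scheme = scheme,
              tp = sum(per$n_malignant[per$positive]),
              fp = sum(per$n_benign[per$positive]),
              tn = sum(per$n_benign[!per$positive]),
              fn = sum(per$n_malignant[!per$positive]),
              n = length(cat))
  class(res) <- "lnrads_confusion"
  res
}

#' @export
print.lnrads_confusion <- function(x, ...) {
  cat(sprintf("LN-RADS confusion summary (%s scheme, n = %d)\n",
              x$scheme, x$n))
  print(x$per_category, row.names = FALSE)
  cat(sprintf("TP %d  FP %d  TN %d  FN %d\n", x$tp, x$fp, x$tn, x$fn))
  invisible(x)
}

# Internal: one metric row with Wilson CI, or an undefined marker.
metric_row <- function(name, k, n, level, method) {
  if (n == 0) {
    return(data.frame(metric = name, estimate = NA_real_, lower = NA_real_,
                      upper = NA_real_, k = NA_integer_, n = 0L,
                      note = "undefined: zero denominator"))
  }
  ci <- proportion_ci(k, n, level, method)
  data.frame(metric = name, estimate = k / n, lower = ci$lower,
             upper = ci$upper, k = as.integer(k), n = as.integer(n),
             note = "")
}

#' Diagnostic accuracy metrics with confidence intervals
#'
#' Sensitivity, specificity, accuracy, PPV and NPV from a confusion
#' summary, each with a binomial confidence interval. A metric whose
#' denominator is zero is reported as undefined (NA with a reason), never
#' fabricated.
#'
#' @param cm An `lnrads_confusion` from [confusion_summary()].
#' @param level Confidence level, default 0.95.
#' @param method Interval method, see [proportion_ci()].
#' @return Data frame with columns `metric`, `estimate`, `lower`, `upper`,
#'   `k`, `n`, `note`.
#' @export
diagnostic_metrics <- function(cm, level = 0.95,
                               method = c("wilson", "clopper-pearson")) {
  method <- match.arg(method)
  stopifnot(inherits(cm, "lnrads_confusion"))
  rbind(
    metric_row("sensitivity", cm$tp, cm$tp + cm$fn, level, method),
    metric_row("specificity", cm$tn, cm$tn + cm$fp, level, method),
    metric_row("accuracy", cm$tp + cm$tn, cm$n, level, method),
    metric_row("ppv", cm$tp, cm$tp + cm$fp, level, method),
    metric_row("npv", cm$tn, cm$tn + cm$fn, level, method))
}

#' Malignancy risk per group
#'
#' Malignant fraction with Wilson interval for each distinct group label —
#' used for the per-category risk profile and for vascular-pattern
#' histopathology correlations alike.
#'
#' @param groups Vector of group labels (factor order respected).
#' @param truth Vector of `"benign"` / `"malignant"`, same length.
#' @param level Confidence level for the Wilson interval.
#' @return Data frame: `group`, `n`, `n_malignant`, `risk`, `lower`, `upper`.
#' @export
risk_by_group <- function(groups, truth, level = 0.95) {
  truth <- as.character(truth)
  if (length(groups) != length(truth)) {
    stop("risk_by_group: groups and truth differ in length")
  }
  g <- if (is.factor(groups)) droplevels(groups) else factor(groups)
  n <- as.integer(table(g))
  n_mal <- as.integer(table(g[truth == "malignant"]))
  ci <- proportion_ci(n_mal, n, level)
  data.frame(group = levels(g), n = n, n_malignant = n_mal,
             risk = n_mal / n, lower = ci$lower, upper = ci$upper)
}

#' Sensitivity stratified by neoplasm cohort
#'
#' Among histopathologically malignant nodes carrying a cohort tag, the
#' fraction classified test-positive under the chosen scheme, per cohort.
#'
#' @param categories Vector coercible by [lnrads_factor()].
#' @param truth Vector of `"benign"` / `"malignant"`.
#' @param cohorts Cohort tags (NA allowed; malignant cohorts analysed).
#' @param scheme Binarization scheme, see [binarize()].
#' @param level Confidence level for the Wilson interval.
#' @return Data frame: `cohort`, `n`, `n_positive`, `sensitivity`,
#'   `lower`, `upper`.
#' @export
cohort_sensitivity <- function(categories, truth, cohorts,
                               scheme = c("statistical", "management"),
                               level = 0.95) {
  scheme <- match.arg(scheme)
  truth <- as.character(truth)
  cohorts <- as.character(cohorts)
  stopifnot(length(categories) == length(truth),
            length(truth) == length(cohorts))
  keep <- !is.na(cohorts) & cohorts %in% cohorts_malignant()
  if (!any(keep)) stop("cohort_sensitivity: no malignant-cohort records")
  if (any(truth[keep] != "malignant")) {
    stop("cohort_sensitivity: malignant cohort tag on a non-malignant record")
  }
  pos <- binarize(categories, scheme) == "positive"
  g <- factor(cohorts[keep],
              levels = intersect(cohorts_malignant(), cohorts[keep]))
  n <- as.integer(table(g))
  n_pos <- as.integer(table(g[pos[keep]]))
  ci <- proportion_ci(n_pos, n, level)
  data.frame(cohort = levels(g), n = n, n_positive = n_pos,
             sensitivity = n_pos / n, lower = ci$lower, upper = ci$upper)
}
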