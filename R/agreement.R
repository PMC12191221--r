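# Inter-rater reliability: Cohen's kappa with large-sample interval,
# percent agreement, and the conventional interpretation bands.

#' Interpretation band for a kappa value
#'
#' Conventional bands: values at or below 0 indicate no agreement beyond
#' chance; then slight (up to 0.20), fair (to 0.40), moderate (to 0.60),
#' substantial (to 0.80) and almost perfect (to 1.00), upper bounds
#' inclusive.
#'
#' @param kappa Numeric vector in `[-1, 1]`.
#' @return Character vector of band labels.
#' @export
interpret_kappa <- function(kappa) {
  stopifnot(all(is.na(kappa) | (kappa >= -1 & kappa <= 1)))
  cut_pts <- c(-Inf, 0, 0.2, 0.4, 0.6, 0.8, 1)
  labs <- c("none", "slight", "fair", "moderate", "substantial",
            "almost_perfect")
  as.character(cut(kappa, cut_pts, labs, right = TRUE))
}

#' Cohen's kappa between two raters
#'
#' Chance-corrected agreement over the cross-table of the two rating
#' vectors: kappa = (p_o - p_e) / (1 - p_e) with expected agreement from
#' the marginal products. The standard error is the large-sample
#' (Fleiss-Cohen-Everitt) one and the interval is Wald, clipped to
#' `[-1, 1]`. Weighted variants (linear/quadratic disagreement weights)
#' are available but off by default; the interpretation bands assume the
#' unweighted statistic.
#'
#' @param ratings_a,ratings_b Equal-length rating vectors; LN-RADS
#'   category factors keep their six levels, otherwise the union of
#'   observed labels is used.
#' @param level Confidence level, default 0.95.
#' @param weighting `"none"` (default), `"linear"` or `"quadratic"`.
#' @return Object of class `lnrads_kappa`: list with `kappa`, `se`,
#'   `lower`, `upper`, `percent_agreement`, `band`, `n`, `weighting`,
#'   `table`, `note`. Degenerate marginals (p_e = 1) yield `kappa = NA`
#'   with an explanatory note.
#' @examples
#' cohens_kappa(c(1, 1, 2, 2), c(1, 2, 2, 2))  # kappa 0.5
#' @export
cohens_kappa <- function(ratings_a, ratings_b, level = 0.95,
                         weighting = c("none", "linear", "quadratic")) {
  weighting <- match.arg(weighting)
  if (length(ratings_a) != length(ratings_b)) {
    stop("cohens_kappa: rating vectors differ in length")
  }
  n <- length(ratings_a)
  if (n < 2L) stop("cohens_kappa: need at least 2 paired ratings")
  if (is.factor(ratings_a) || is.factor(ratings_b)) {
    lev <- union(levels(factor(ratings_a)), levels(factor(ratings_b)))
  } else {
    lev <- sort(union(unique(as.character(ratings_a)),
                      unique(as.character(ratings_b))))
  }
  a <- factor(as.character(ratings_a), levels = lev)
  b <- factor(as.character(ratings_b), levels = lev)
  if (any(is.na(a)) || any(is.na(b))) stop("cohens_kappa: NA ratings")
  tab <- table(a, b)
  p <- tab / n
  k <- length(lev)
  # similarity weights: identity for unweighted
  idx <- seq_len(k)
  dist <- abs(outer(idx, idx, "-")) / max(1, k - 1)
  w <- switch(weighting,
              none = diag(k) * 1,
              linear = 1 - dist,
              quadratic = 1 - dist^2)
  pi_ <- rowSums(p); pj <- colSums(p)
  po <- sum(w * p)
  pe <- sum(w * outer(pi_, pj))
  percent_agreement <- sum(diag(p))
  if (1 - pe < .Machine$double.eps^0.5) {
    res <- list(kappa = NA_real_, se = NA_real_, lower = NA_real_,
                upper = NA_real_, percent_agreement = percent_agreement,
                band = NA_character_, n = n, weighting = weighting,
                table = tab,
                note = "undefined: degenerate marginals give p_e = 1")
    class(res) <- "lnrads_kappa"
    return(res)
  }
  kap <- (po - pe) / (1 - pe)
  # large-sample variance (Fleiss, Cohen & Everitt), general weighted form
  wbar_i <- as.vector(w %*% pj)   # row-wise expected weight
  wbar_j <- as.vector(pi_ %*% w)  # column-wise expected weight
  pen <- outer(wbar_i, wbar_j, "+") * (1 - kap)
  var_k <- (sum(p * (w - pen)^2) - (kap - pe * (1 - kap))^2) /
    (n * (1 - pe)^2)
  se <- sqrt(max(0, var_k))
  z <- stats::qnorm(1 - (1 - level) / 2)
  res <- list(kappa = kap, se = se,
              lower = max(-1, kap - z * se), upper = min(1, kap + z * se),
              percent_agreement = percent_agreement,
              band = interpret_kappa(kap), n = n, weighting = weighting,
              table = tab, note = "")
  class(res) <- "lnrads_kappa"
  res
}

#' @export
print.lnrads_kappa <- function(x, ...) {
  if (is.na(x$kappa)) {
    cat("Cohen's kappa: undefined (", x$note, ")\n", sep = "")
  } else {
    cat(sprintf("Cohen's kappa (%s): %.3f (95%% CI %.3f-%.3f), %s agreement\n",
                x$weighting, x$kappa, x$lower, x$upper,
                gsub("_", " ", x$band)))
    cat(sprintf("percent agreement %.1f%% over n = %d\n",
                100 * x$percent_agreement, x$n))
  }
  invisible(x)
}

#' Pairwise agreement among several readers
#'
#' Cohen's kappa, its interval and the band for every unordered pair of
#' readers.
#'
#' @param ratings_by_reader Named list of equal-length rating vectors, or a
#'   data frame with one column per reader.
#' @param level Confidence level passed to [cohens_kappa()].
#' @param weighting Weighting passed to [cohens_kappa()].
#' @return Data frame with one row per pair: `reader_a`, `reader_b`,
#'   `kappa`, `se`, `lower`, `upper`, `percent_agreement`, `band`.
#' @export
pairwise_agreement <- function(ratings_by_reader, level = 0.95,
                               weighting = "none") {
  r <- as.list(ratings_by_reader)
  if (length(r) < 2L) stop("pairwise_agreement: need at least two readers")
  if (length(unique(vapply(r, length, integer(1)))) != 1L) {
    stop("pairwise_agreement: rating vectors differ in length")
  }
  nm <- names(r)
  if (is.null(nm)) nm <- paste0("reader_", seq_along(r))
  pairs <- utils::combn(seq_along(r), 2)
  rows <- apply(pairs, 2, function(ij) {
    k <- cohens_kappa(r[[ij[1]]], r[[ij[2]]], level, weighting)
    data.frame(reader_a = nm[ij[1]], reader_b = nm[ij[2]],
               kappa = k$kappa, se = k$se, lower = k$lower, upper = k$upper,
               percent_agreement = k$percent_agreement, band = k$band)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
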