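# Exhaustive pairwise-concordance oracle for the AUC.
auc_oracle <- function(values, truth, direction = "higher_is_malignant") {
  s <- if (direction == "higher_is_malignant") values else -values
  x <- s[truth == "malignant"]; y <- s[truth == "benign"]
  tot <- 0
  for (xi in x) for (yj in y) {
    tot <- tot + (xi > yj) + 0.5 * (xi == yj)
  }
  tot / (length(x) * length(y))
}

# Brute-force scan over every distinct value for the Youden optimum.
youden_oracle <- function(values, truth, direction = "higher_is_malignant") {
  mal <- truth == "malignant"
  best <- NULL
  for (t in sort(unique(values),
                 decreasing = direction == "lower_is_malignant")) {
    pos <- if (direction == "higher_is_malignant") values >= t
    else values <= t
    j <- mean(pos[mal]) + mean(!pos[!mal]) - 1
    if (is.null(best) || j > best$j ||
        (j == best$j &&
         ((direction == "higher_is_malignant" && t < best$t) ||
          (direction == "lower_is_malignant" && t > best$t)))) {
      best <- list(t = t, j = j)
    }
  }
  best
}

rand_instance <- function(n, tie_prob = 0.3) {
  values <- if (runif(1) < tie_prob) sample(1:5, n, replace = TRUE)
  else round(rnorm(n, 10, 3), 1)
  truth <- sample(c("benign", "malignant"), n, replace = TRUE)
  if (length(unique(truth)) < 2) truth[1:2] <- c("benign", "malignant")
  list(values = values, truth = truth)
}

test_that("ROC points match exhaustive cutoff enumeration", {
  values <- c(0.1, 0.4, 0.35, 0.8)
  truth <- c("benign", "benign", "malignant", "malignant")
  pts <- roc_points(values, truth)
  # 4 distinct cutoffs + endpoints; the lowest cutoff coincides with (1,1)
  expect_identical(nrow(pts), 5L)
  # brute force: at every cutoff t, (fpr, tpr) for rule value >= t
  for (i in seq_len(nrow(pts))) {
    t <- pts$threshold[i]
    expect_equal(pts$tpr[i], mean(values[truth == "malignant"] >= t))
    expect_equal(pts$fpr[i], mean(values[truth == "benign"] >= t))
  }
  expect_true(all(diff(pts$fpr) >= 0) && all(diff(pts$tpr) >= 0))
})

test_that("degenerate ROC shapes behave", {
  # perfect separation passes through (0, 1)
  pts <- roc_points(c(1, 2, 8, 9), c("benign", "benign",
                                     "malignant", "malignant"))
  expect_true(any(pts$fpr == 0 & pts$tpr == 1))
  # identical values: only the endpoints, the diagonal
  pts <- roc_points(rep(3, 6), rep(c("benign", "malignant"), 3))
  expect_identical(nrow(pts), 2L)
  expect_equal(pts$fpr, pts$tpr)
  expect_error(roc_points(1:4, rep("benign", 4)), "single-class")
})

test_that("AUC equals the pairwise concordance count", {
  expect_equal(roc_auc(c(0.1, 0.4, 0.35, 0.8),
                       c("benign", "benign", "malignant", "malignant"))$auc,
               0.75)
  expect_equal(roc_auc(c(1, 2, 8, 9), c("benign", "benign",
                                        "malignant", "malignant"))$auc, 1)
  withr::with_seed(41, {
    for (i in 1:25) {
      inst <- rand_instance(sample(4:50, 1))
      dir <- sample(c("higher_is_malignant", "lower_is_malignant"), 1)
      expect_equal(roc_auc(inst$values, inst$truth, dir)$auc,
                   auc_oracle(inst$values, inst$truth, dir),
                   tolerance = 1e-12)
    }
  })
})

test_that("AUC equals the trapezoidal area under the empirical curve", {
  withr::with_seed(43, {
    for (i in 1:10) {
      inst <- rand_instance(40)
      pts <- roc_points(inst$values, inst$truth)
      trap <- sum(diff(pts$fpr) * (head(pts$tpr, -1) + tail(pts$tpr, -1)) / 2)
      expect_equal(roc_auc(inst$values, inst$truth)$auc, trap,
                   tolerance = 1e-12)
    }
  })
})

test_that("direction inversion mirrors the AUC", {
  withr::with_seed(47, {
    inst <- rand_instance(60)
    a_hi <- roc_auc(inst$values, inst$truth, "higher_is_malignant")$auc
    a_lo <- roc_auc(inst$values, inst$truth, "lower_is_malignant")$auc
    expect_equal(a_hi, 1 - a_lo, tolerance = 1e-12)
  })
})

test_that("AUC and DeLong interval agree with an independent implementation", {
  skip_if_not_installed("pROC")
  withr::with_seed(53, {
    for (i in 1:5) {
      n <- 80
      truth <- rep(c("benign", "malignant"), each = n / 2)
      values <- rnorm(n, ifelse(truth == "malignant", 1, 0))
      mine <- roc_auc(values, truth)
      ref <- pROC::roc(truth, values, levels = c("benign", "malignant"),
                       direction = "<", quiet = TRUE)
      ci <- pROC::ci.auc(ref, method = "delong")
      expect_equal(mine$auc, as.numeric(pROC::auc(ref)), tolerance = 1e-12)
      expect_equal(c(mine$lower, mine$upper), as.numeric(ci[c(1, 3)]),
                   tolerance = 1e-9)
    }
  })
})

test_that("the Youden optimum matches the brute-force scan", {
  r <- youden_optimal(c(4, 5, 6, 8, 9, 10),
                      rep(c("benign", "malignant"), each = 3))
  expect_equal(r$threshold, 8)
  expect_equal(r$youden_j, 1)

  r <- youden_optimal(c(2, 9, 8, 15),
                      c("benign", "benign", "malignant", "malignant"))
  expect_equal(r$threshold, 8)
  expect_equal(r$sensitivity, 1)
  expect_equal(r$specificity, 0.5)
  expect_equal(r$youden_j, 0.5)

  r <- youden_optimal(rep(2, 8), rep(c("benign", "malignant"), 4))
  expect_equal(r$youden_j, 0)

  withr::with_seed(59, {
    for (i in 1:25) {
      inst <- rand_instance(sample(4:40, 1))
      dir <- sample(c("higher_is_malignant", "lower_is_malignant"), 1)
      mine <- youden_optimal(inst$values, inst$truth, dir)
      oracle <- youden_oracle(inst$values, inst$truth, dir)
      expect_equal(mine$youden_j, oracle$j, tolerance = 1e-12)
      expect_equal(mine$threshold, oracle$t)
      expect_equal(mine$youden_j, mine$sensitivity + mine$specificity - 1,
                   tolerance = 1e-12)
    }
  })
})

test_that("the feature panel runs the documented directions", {
  cohort <- generate_cohort(cohort_spec(seed = 3))  # full default composition
  panel <- feature_panel(cohort)
  expect_identical(panel$direction[panel$feature == "MTD/(MTD+CTD) ratio"],
                   "lower_is_malignant")
  # cortical thickness is the strongest single predictor on synthetic data
  cont <- panel[panel$feature != "Vascular pattern", ]
  expect_identical(cont$feature[which.max(cont$auc)], "CTD")
  # vascular pattern analysed only over the Doppler subset
  vp <- panel[panel$feature == "Vascular pattern", ]
  expect_identical(vp$n_benign + vp$n_malignant,
                   sum(!is.na(cohort$vascular_pattern)))

  # separation by construction
  shifted <- cohort
  shifted$ctd_mm <- shifted$ctd_mm +
    ifelse(shifted$histopathology == "malignant", 100, 0)
  shifted$sad_mm <- pmax(shifted$sad_mm, shifted$ctd_mm)
  shifted$lad_mm <- pmax(shifted$lad_mm, shifted$sad_mm)
  p2 <- feature_panel(shifted)
  expect_equal(p2$auc[p2$feature == "CTD"], 1)

  benign_only <- cohort[cohort$histopathology == "benign", ]
  expect_error(feature_panel(benign_only), "single-class")
})
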