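test_that("the study composition collapses to the published confusion counts", {
  s <- study_composition()
  cm <- confusion_summary(s$categories, s$truth, "statistical")
  expect_identical(c(cm$tp, cm$fp, cm$tn, cm$fn), c(346L, 49L, 281L, 43L))
  expect_identical(cm$n, 719L)

  cmm <- confusion_summary(s$categories, s$truth, "management")
  expect_identical(cmm$fn, 2L)
  expect_identical(cmm$tp, 387L)
})

test_that("empty input yields an all-zero summary", {
  cm <- confusion_summary(character(0), character(0))
  expect_identical(c(cm$tp, cm$fp, cm$tn, cm$fn, cm$n), rep(0L, 5))
  expect_true(all(cm$per_category$n_benign == 0))
})

test_that("length mismatches and missing truth are rejected", {
  expect_error(confusion_summary(c("1", "2"), "benign"), "length")
  expect_error(confusion_summary("1", NA_character_), "truth")
})

test_that("scheme switch moves exactly the 4a row across the split", {
  s <- study_composition()
  stat <- confusion_summary(s$categories, s$truth, "statistical")
  mgmt <- confusion_summary(s$categories, s$truth, "management")
  row4a <- stat$per_category[stat$per_category$category == "4a", ]
  expect_identical(mgmt$tp - stat$tp, row4a$n_malignant)
  expect_identical(mgmt$fp - stat$fp, row4a$n_benign)
  expect_identical(stat$fn - mgmt$fn, row4a$n_malignant)
  expect_identical(stat$tn - mgmt$tn, row4a$n_benign)
  # conservation
  expect_identical(sum(stat$per_category$n_benign +
                         stat$per_category$n_malignant), stat$n)
})

test_that("diagnostic metrics reproduce the headline accuracy block", {
  s <- study_composition()
  m <- diagnostic_metrics(confusion_summary(s$categories, s$truth))
  est <- setNames(m$estimate, m$metric)
  expect_equal(unname(est["sensitivity"]), 346 / 389)
  expect_identical(pct_half_up(est["sensitivity"]), c(sensitivity = 89))
  expect_identical(pct_half_up(est["specificity"]), c(specificity = 85))
  expect_identical(pct_half_up(est["accuracy"]), c(accuracy = 87))
  expect_identical(pct_half_up(est["ppv"]), c(ppv = 88))
  sens <- m[m$metric == "sensitivity", ]
  expect_identical(pct_half_up(c(sens$lower, sens$upper)), c(85, 92))
})

test_that("degenerate confusion tables give exact or undefined metrics", {
  cm <- confusion_summary(rep(c("5", "1"), c(3, 4)),
                          rep(c("malignant", "benign"), c(3, 4)))
  m <- diagnostic_metrics(cm)
  expect_true(all(m$estimate == 1))

  cm <- confusion_summary(c("5", "5", "1", "1"),
                          c("malignant", "benign", "malignant", "benign"))
  m <- diagnostic_metrics(cm)
  expect_true(all(m$estimate == 0.5))
  # hand evaluation of the score interval at p-hat = 1/2, n = 2
  z <- qnorm(0.975)
  denom <- 1 + z^2 / 2
  half <- z / denom * sqrt(0.125 + z^2 / 16)
  centre <- (0.5 + z^2 / 4) / denom
  sens <- m[m$metric == "sensitivity", ]
  expect_equal(c(sens$lower, sens$upper), c(centre - half, centre + half))

  # zero denominator reported as undefined, not fabricated
  cm0 <- confusion_summary(c("1", "1"), c("benign", "benign"))
  m0 <- diagnostic_metrics(cm0)
  expect_true(is.na(m0$estimate[m0$metric == "sensitivity"]))
  expect_match(m0$note[m0$metric == "sensitivity"], "undefined")
})

test_that("the Wilson interval matches the inverted score test", {
  withr::with_seed(17, {
    for (i in 1:100) {
      n <- sample(1:500, 1)
      k <- sample(0:n, 1)
      ci <- proportion_ci(k, n)
      expect_equal(c(ci$lower, ci$upper), wilson_oracle(k, n),
                   tolerance = 1e-12)
    }
  })
  expect_identical(proportion_ci(0, 50)$lower, 0)
  ci <- proportion_ci(346, 389)
  expect_identical(pct_half_up(c(ci$lower, ci$upper)), c(85, 92))
})

test_that("the Wilson interval shrinks with n at fixed proportion", {
  w1 <- proportion_ci(20, 50)
  w2 <- proportion_ci(200, 500)
  expect_lt(w2$upper - w2$lower, w1$upper - w1$lower)
})

test_that("the Clopper-Pearson option matches binom.test", {
  withr::with_seed(23, {
    for (i in 1:20) {
      n <- sample(2:300, 1)
      k <- sample(0:n, 1)
      ci <- proportion_ci(k, n, method = "clopper-pearson")
      bt <- binom.test(k, n)$conf.int
      expect_equal(c(ci$lower, ci$upper), c(bt[1], bt[2]), tolerance = 1e-12)
    }
  })
})

test_that("per-group malignancy risk reproduces the published profile", {
  s <- study_composition()
  r <- risk_by_group(s$categories, s$truth)
  risk <- setNames(r$risk, r$group)
  expect_identical(pct_half_up(risk[c("3", "4b", "5")]),
                   c("3" = 2, "4b" = 77, "5" = 97))
  expect_equal(unname(risk["5"]), 204 / 211)

  # the vascular-pattern correlation table is the same computation
  vasc <- risk_by_group(rep(2, 51), rep(c("benign", "malignant"), c(36, 15)))
  expect_equal(vasc$risk, 15 / 51)
  expect_identical(pct_half_up(vasc$risk), 29)
})

test_that("sensitivity aggregates the positive-category risks", {
  s <- study_composition()
  r <- risk_by_group(s$categories, s$truth)
  cm <- confusion_summary(s$categories, s$truth, "statistical")
  m <- diagnostic_metrics(cm)
  pos <- r$group %in% c("4b", "5")
  agg <- sum(r$n[pos] * r$risk[pos]) / sum(s$truth == "malignant")
  expect_equal(agg, m$estimate[m$metric == "sensitivity"])
})

test_that("cohort-stratified sensitivity matches the printed cohort counts", {
  mel <- rep(c("4a", "4b", "5"), c(3, 15, 30))
  cs <- cohort_sensitivity(mel, rep("malignant", 48),
                           rep("melanoma_sarcoma", 48))
  expect_equal(cs$sensitivity, 45 / 48)
  expect_identical(pct_half_up(cs$sensitivity), 94)

  leu <- rep(c("3", "4a", "4b", "5"), c(1, 8, 22, 62))
  cs <- cohort_sensitivity(leu, rep("malignant", 93),
                           rep("leukemia_lymphoma", 93))
  expect_equal(cs$sensitivity, 84 / 93)
  expect_identical(pct_half_up(cs$sensitivity), 90)

  cs <- cohort_sensitivity(rep("5", 10), rep("malignant", 10),
                           rep("cancer", 10))
  expect_equal(cs$sensitivity, 1)

  expect_error(cohort_sensitivity("4b", "benign", "cancer"), "non-malignant")
  expect_error(cohort_sensitivity("4b", "benign", NA_character_), "no malignant")
})
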