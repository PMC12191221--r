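---
title: "LN-RADS in lnrads: the rule cascade, its evaluation statistics, and the synthetic cohort model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{LN-RADS in lnrads: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lnrads)
```

## The problem

Sonographic assessment of superficial lymph nodes (neck, periclavicular
region, axilla, groin) traditionally leans on a single size criterion —
most often a 10 mm short-axis cutoff — which misses small metastases and
over-calls large reactive nodes. LN-RADS is a BI-RADS-style ordinal
reporting scale that instead combines morphometrics, subjective grey-scale
grades, architectural findings, Doppler architecture and clinical context
into six categories (1, 2, 3, 4a, 4b, 5) with attached malignancy-risk
estimates. `lnrads` formalises that scale as a deterministic rule engine
and implements the statistical toolkit used to validate it against
histopathology.

## The record model

A node record carries four lengths in millimetres — short-axis diameter
(SAD), long-axis diameter (LAD), maximal cortical thickness (CTD) and
medullary/hilar thickness (MTD) — five subjective grades on a 1–5 ordinal
scale (shape, cortical irregularity, echogenicity, inhomogeneity,
borders), an optional Doppler vascular pattern (1 no flow, 2 hilar "small
tree", 3 hilar-cortical "big tree", 4 peripheral, 5 chaotic), boolean
architectural findings, and six boolean clinical-context flags. Grade 1
is always the most benign pole of each scale. Two derived ratios are used
throughout:

* `s_over_l = SAD / LAD`, roundness; a node is *oval* when S/L < 0.5
  (equivalently L/S > 2);
* `medulla_fraction = MTD / (MTD + CTD)`, the share of the
  cortex-plus-medulla thickness occupied by the medulla.

`MTD = 0` is the canonical encoding of an invisible hilum, and the
boolean `hilum_present` must agree with it in both directions; the
validator flags any disagreement. Lengths are accepted to 0.1 mm
precision and never re-rounded internally, so threshold comparisons at
integer and 0.01-level cutoffs are exact. A missing vascular pattern is a
first-class state (Doppler not performed, as in roughly two thirds of
real examinations) and is never imputed.

## The rule cascade

`classify_nodes()` evaluates rules malignant-first and returns on the
first match:

1. **R5_EXTRACAPSULAR** — extracapsular infiltration forces category 5.
   It is an unequivocal invasion sign listed only for the top category.
2. **R5_ENLARGED_HIGH_RISK** — SAD strictly above
   `sad_enlarged_min_mm` (default 9 mm) *and* at least
   `high_risk_count_for_5` (default 2) malignant features gives 5.
3. **R4B_HIGH_RISK** — any malignant feature gives 4b.
4. **R1_NORMAL**, **R2_STEATOTIC**, **R3_REACTIVE** — the benign screens.
5. **R4A_FALLBACK** — everything else is 4a ("better check than miss";
   the 4a category is defined negatively as whatever matches neither the
   benign screens nor the high-risk rules).

The malignant-feature list scanned by rules 2–3 is: cortex thicker than
`ctd_4b_min_mm` (default 4 mm, strict) *with* irregularity grade ≥ 3;
focal cortical thickening; absent hilum; round shape (S/L ≥ 0.5); deep
hypoechogenicity (grade ≥ 4, toward the anechoic "black hole sign");
microcalcifications; fluid collections; necrosis; peripheral or chaotic
vascularization (patterns 4–5); and blurred margins (grade ≥ 4).

Design points that the scale's prose leaves open, resolved here once:

* **"Up to 6–7 mm" normal SAD** — the permissive end (7 mm) is the
  default `sad_normal_max_mm`; it is a plain configuration field.
* **"Enlargement in SAD" for category 5** — defaulted to > 9 mm, the
  optimal single-feature short-axis cutoff in the validation data, rather
  than the conventional 10 mm; configurable.
* **"More malignancy features" for category 5** — operationalised as a
  count threshold (default 2), configurable.
* **Local cortical thickening (LCT)** — blocks the R1/R2 "clean
  architecture" screens; R3 tolerates it as long as the irregularity
  grade stays ≤ 2, so LCT with visible irregularity falls through to 4a.
* **Boundaries** — every "over X mm" is strict (`>`), every "maximum
  X mm" inclusive (`≤`), mirroring the scale's wording.
* **Clinical flags** — any flag blocks the benign screens, so
  reactive-looking morphology with, say, an active regional neoplasm
  lands in exactly 4a. Clinical context alone can never produce 4b or 5.
* The ROC-derived S/L cutoff of 0.51 reported for the single-feature
  analysis is deliberately *not* used inside the classifier; the scale's
  own 0.5 definition of oval is. The threshold module reports whatever
  the data yield.

Two binarization schemes collapse the scale for accuracy statistics:
*statistical* (positive = 4b–5; category 4a's observed risk is below one
half, so it counts as test-negative) and *management* (positive = 4a–5;
everything that warrants biopsy or PET workup).

## Evaluation statistics

`confusion_summary()` tallies benign/malignant histopathology per
category and collapses to TP/FP/TN/FN under a scheme.
`diagnostic_metrics()` reports sensitivity, specificity, accuracy, PPV
and NPV. Proportion intervals are **Wilson score** intervals by default
(Clopper–Pearson behind a flag): the validation study does not name its
interval method, and Wilson reproduces the printed integer-percent
interval bounds from the published counts in nine of ten positions — the
one exception (the specificity upper bound) is not reproducible from the
published counts by *any* standard binomial interval, so it is treated as
a printing inconsistency. Metrics with zero denominators are reported as
undefined with a reason, never as 0 or 1. Display rounding is half-up to
integer percent; internal values are never rounded.

`risk_by_group()` computes the malignant fraction with its Wilson
interval for arbitrary grouping labels — the per-category risk profile
and the vascular-pattern correlation table are the same computation.
`cohort_sensitivity()` stratifies sensitivity by neoplasm cohort
(carcinoma, leukemia/lymphoma, melanoma/sarcoma, nonspecific).

## Per-feature thresholds

`roc_points()` / `roc_auc()` / `youden_optimal()` implement empirical
ROC analysis with these conventions:

* candidate cutoffs are the **distinct observed values** (not
  midpoints), which reproduces integer-millimetre thresholds naturally;
* positivity is `value ≥ t` for higher-is-malignant features and
  `value ≤ t` for lower-is-malignant ones;
* the AUC is the rank-based concordance probability with tied
  benign–malignant pairs counted one half, and its interval is the
  DeLong asymptotic one from the placement-value variances;
* the Youden optimum maximises J = sensitivity + specificity − 1, with
  ties broken toward the more sensitive cutoff (smallest threshold under
  higher-is-malignant, largest under lower-is-malignant);
* `feature_panel()` analyses LAD, SAD, S/L and CTD as
  higher-is-malignant, the medulla fraction as lower-is-malignant, and
  the vascular pattern only over nodes with a Doppler study.

The published per-feature threshold table cannot be reproduced at the
desk because the per-node raw data were never released; the package
instead verifies the *directional* finding — cortical thickness is the
strongest single continuous predictor — on synthetic cohorts, and checks
the estimators themselves against brute-force oracles (exhaustive
pairwise concordance, exhaustive cutoff scans).

## Inter-rater agreement

`cohens_kappa()` computes unweighted Cohen's kappa over the six-category
cross-table, with the large-sample (Fleiss–Cohen–Everitt) standard error
and a Wald interval clipped to [−1, 1]; percent agreement is reported
alongside. Unweighted kappa is the default because the conventional
interpretation bands (slight ≤ 0.20 < fair ≤ 0.40 < moderate ≤ 0.60 <
substantial ≤ 0.80 < almost perfect) assume it; linear and quadratic
disagreement weights are available behind a flag. Degenerate marginals
(expected agreement 1) yield an explicitly undefined kappa. The published
study-level kappas require per-node reader data that were not released;
agreement machinery is therefore validated by a reader-noise recovery
property (below) and by exhaustive small-table oracles.

## The synthetic cohort generator

`generate_cohort()` emulates the validation study's structure so the
whole pipeline is testable without patient data. Its defaults *are* the
study conditions:

* group sizes 330 benign / 233 carcinoma / 93 leukemia–lymphoma /
  48 melanoma–sarcoma / 17 nonspecific (the published per-cohort sizes);
* per-group LAD/SAD/CTD/MTD means and SDs equal to the published
  group-level morphometry table;
* vascular-pattern mixtures equal to the published Doppler correlation
  counts (benign 8/36/11/17/7 of 79; malignant 9/15/13/60/62 of 159),
  applied to a Doppler fraction of 238/719;
* subjective grades drawn by rounding a unit-SD latent centred at 2 for
  benign nodes and 2 + `grade_shift` (default 1.5) for malignant ones,
  clamped to 1–5. The published tables give no grade moments, so the
  latent centre and shift are realism choices: they put roughly two
  thirds of benign nodes at grades ≤ 2 and centre malignant nodes
  between grades 3 and 4;
* finding rates (e.g. focal cortical thickening in 30% of malignant and
  1% of benign nodes) and clinical-flag rates (0.03 per flag for benign
  nodes, 0.35 for malignant groups) are likewise realism choices fixed
  once and documented here; they are not published quantities.

Morphometrics are sampled per feature from normals truncated at zero
(conditionally for SAD/LAD/CTD, which must be positive; censored at zero
for MTD, because the point mass at zero is exactly the absent-hilum
state) and then repaired to the record invariants: LAD := max(LAD, SAD),
CTD := min(CTD, SAD), MTD := min(MTD, SAD). Truncation and repair bias
naive means, so each location parameter is calibrated by a
common-random-number search (`optimize` over the location, against a
fixed 20 000-draw calibration sample with its own internal seed) so that
the *realised post-repair* mean matches the target. Two targets sit on
the boundary of what any repair permits — the melanoma/sarcoma group's
published CTD mean equals its SAD mean, so calibration drives CTD to the
SAD ceiling — and the search then settles at the closest reachable mean,
which is within Monte-Carlo error of the target. Repairing MTD against
SAD alone (rather than against the leftover SAD − CTD) is deliberate:
the record model only requires MTD ≤ SAD, and coupling MTD to SAD − CTD
would make several published group means (benign MTD, melanoma MTD)
unreachable in principle.

What the generator does **not** model, and what that implies: features
are drawn independently within a group (no published correlation
structure), so jointly unusual combinations — e.g. round benign nodes,
because SAD and LAD are drawn independently — are more common than in
real cohorts. Synthetic specificity is therefore lower than the
published one, and passing pipeline tests on synthetic data demonstrates
correctness of the *machinery* (classification, counting, intervals,
ROC, kappa), not clinical performance on real nodes. Variances are not
jointly matched after repair; means are prioritised.

`generate_reader_panel()` models inter-reader noise as an
adjacent-category kernel: each reader keeps each base category with
probability 1 − p and otherwise moves one step along the ordinal scale
(equal probability each way, reflecting at the ends). RADS-style
disagreements are predominantly adjacent-category, which this kernel
captures with a single parameter. The kernel's implied kappa is
closed-form (for a base uniform over the six categories, p = 0.2 gives
κ ≈ 0.656), giving a sharp recovery target for the agreement machinery.

All randomness flows from explicit seeds; generation restores the
caller's RNG state, and identical spec plus seed gives bytewise-identical
CSV output.

## Numerical choices and degenerate inputs

* Ratios are exact divisions; `derive_ratios` errors when
  MTD + CTD = 0 or LAD = 0 rather than returning NaN.
* Wilson bounds are clipped to [0, 1]; kappa's Wald bounds to [−1, 1].
* Single-class inputs (no benign or no malignant) are errors in every
  ROC routine, propagated per feature by `feature_panel()`.
* The classifier is a pure function: no RNG, no state, bytewise-stable
  outputs; ties cannot occur because rule precedence is total.
* Calibration tolerance is 10⁻⁴ of a feature SD; the calibration sample
  (20 000 draws) keeps its Monte-Carlo error an order of magnitude below
  the 2-standard-error acceptance band at n = 4000.

## Problem sizes used in the test-suite

Property tests run on a few hundred randomised records per block;
generator recovery uses 4000 nodes per group (the size at which a
2-standard-error band on a group mean is ±0.06–0.37 mm depending on the
feature SD); reader-panel recovery uses 5000 ratings, where the ±0.03
band around the kernel-implied kappa is about three empirical standard
errors. These sizes were chosen so every stochastic check is sharp at
fixed seeds while the whole suite stays fast.

## Known limitations

* The rule cascade is a *formalisation* of a heuristic, open scale; the
  published system explicitly allows reader judgement that no rule
  engine reproduces. Per-record agreement with the study's readers is
  not claimable — only agreement with the published aggregate tables is
  testable, and that is what the acceptance surface checks.
* Elastography is not modelled (not statistically assessed in the
  validation study), and no image-derived features are computed —
  features are inputs.
* The synthetic generator matches group means, mixtures and margins,
  not correlations or higher moments.
* Appendix-level wording of the five-point grade scales was not
  available; the ordinal semantics (grade 1 = most benign pole) are
  fixed by this package's documentation.
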