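# Fixtures built in code: a template node, the validation study's
# category/outcome composition, and a random valid-record generator for
# property-style tests.

# One fully consistent record; defaults describe a normal (category 1)
# node. Override any field via ...
make_node <- function(...) {
  node <- data.frame(
    node_id = "n1", region = "axilla",
    sad_mm = 5, lad_mm = 12, ctd_mm = 2, mtd_mm = 3,
    shape_grade = 1, cortex_irregularity_grade = 1, echogenicity_grade = 1,
    inhomogeneity_grade = 1, border_grade = 1, vascular_pattern = 2,
    hilum_present = TRUE, steatotic_hilum = FALSE, fct = FALSE, lct = FALSE,
    microcalcifications = FALSE, fluid_collections = FALSE, necrosis = FALSE,
    extracapsular_infiltration = FALSE,
    oncological_history = FALSE, hematological_history = FALSE,
    active_regional_neoplasm = FALSE, elevated_or_rising_markers = FALSE,
    other_suspicious_regional_ln = FALSE, systemic_symptoms = FALSE,
    histopathology = NA_character_, cohort = NA_character_,
    stringsAsFactors = FALSE)
  over <- list(...)
  for (nm in names(over)) node[[nm]] <- over[[nm]]
  node
}

# The validation study's per-category benign/malignant composition.
study_composition <- function() {
  counts <- data.frame(
    category = c("1", "2", "3", "4a", "4b", "5"),
    benign = c(33, 46, 107, 95, 42, 7),
    malignant = c(0, 0, 2, 41, 142, 204))
  cats <- rep(counts$category, counts$benign + counts$malignant)
  truth <- unlist(mapply(function(b, m) rep(c("benign", "malignant"), c(b, m)),
                         counts$benign, counts$malignant, SIMPLIFY = FALSE))
  list(categories = cats, truth = truth, counts = counts)
}

# Random records that always satisfy the data-model invariants; lengths
# are drawn to 0.1 mm precision.
random_nodes <- function(n, seed = 1) {
  withr::with_seed(seed, {
    sad <- round(runif(n, 2, 25), 1)
    lad <- round(sad * runif(n, 1, 3.5), 1)
    ctd <- round(sad * runif(n, 0.05, 1), 1)
    mtd <- ifelse(runif(n) < 0.3, 0, round(sad * runif(n, 0.05, 1), 1))
    g <- function() as.numeric(sample(1:5, n, replace = TRUE))
    vp <- ifelse(runif(n) < 0.4, NA, as.numeric(sample(1:5, n, replace = TRUE)))
    b <- function(p) runif(n) < p
    hp <- sample(c("benign", "malignant"), n, replace = TRUE)
    nodes <- data.frame(
      node_id = sprintf("r%04d", seq_len(n)),
      region = sample(c("neck", "periclavicular", "axilla", "inguinal"),
                      n, replace = TRUE),
      sad_mm = sad, lad_mm = lad, ctd_mm = ctd, mtd_mm = mtd,
      shape_grade = g(), cortex_irregularity_grade = g(),
      echogenicity_grade = g(), inhomogeneity_grade = g(),
      border_grade = g(), vascular_pattern = vp,
      hilum_present = mtd > 0, steatotic_hilum = mtd > 0 & b(0.3),
      fct = b(0.2), lct = b(0.2), microcalcifications = b(0.1),
      fluid_collections = b(0.1), necrosis = b(0.1),
      extracapsular_infiltration = b(0.05),
      oncological_history = b(0.2), hematological_history = b(0.1),
      active_regional_neoplasm = b(0.1), elevated_or_rising_markers = b(0.1),
      other_suspicious_regional_ln = b(0.1), systemic_symptoms = b(0.1),
      histopathology = hp,
      cohort = ifelse(hp == "benign", "benign",
                      sample(c("cancer", "leukemia_lymphoma",
                               "melanoma_sarcoma", "nonspecific"),
                             n, replace = TRUE)),
      stringsAsFactors = FALSE)
    nodes
  })
}

# Half-up rounding to integer percent (display convention).
pct_half_up <- function(x) floor(100 * x + 0.5)

# Independent Wilson oracle: invert the score test numerically, without
# using the closed form.
wilson_oracle <- function(k, n, level = 0.95) {
  z <- qnorm(1 - (1 - level) / 2)
  p_hat <- k / n
  score <- function(p) (p_hat - p) / sqrt(p * (1 - p) / n)
  lower <- if (k == 0) 0 else
    uniroot(function(p) score(p) - z, c(1e-12, min(p_hat, 1 - 1e-12)),
            tol = 1e-15)$root
  upper <- if (k == n) 1 else
    uniroot(function(p) score(p) + z, c(max(p_hat, 1e-12), 1 - 1e-12),
            tol = 1e-15)$root
  c(lower, upper)
}

# Edits that impose one malignant feature while keeping the record valid;
# NULL when the base record cannot accommodate the edit.
feature_edits <- list(
  CTD_OVER_4B_WITH_IRREGULARITY = function(n) {
    if (n$sad_mm < 4.6) return(NULL)
    n$ctd_mm <- max(n$ctd_mm, 4.6)
    n$cortex_irregularity_grade <- max(n$cortex_irregularity_grade, 3); n
  },
  FCT = function(n) { n$fct <- TRUE; n },
  NO_HILUM = function(n) {
    n$mtd_mm <- 0; n$hilum_present <- FALSE; n$steatotic_hilum <- FALSE; n
  },
  ROUND = function(n) { n$lad_mm <- n$sad_mm * 1.5; n },
  DEEP_HYPOECHOIC = function(n) {
    n$echogenicity_grade <- max(n$echogenicity_grade, 4); n
  },
  MICROCALCIFICATIONS = function(n) { n$microcalcifications <- TRUE; n },
  FLUID = function(n) { n$fluid_collections <- TRUE; n },
  NECROSIS = function(n) { n$necrosis <- TRUE; n },
  ABNORMAL_VASCULARITY = function(n) { n$vascular_pattern <- 5; n },
  BLURRED_MARGINS = function(n) { n$border_grade <- max(n$border_grade, 4); n })

# Analytic kappa implied by the adjacent-step reader-noise kernel on a
# base uniform over the six categories.
kernel_kappa <- function(p) {
  trans <- function(b) {
    pr <- numeric(6)
    pr[b] <- 1 - p
    for (s in c(-1, 1)) pr[min(6, max(1, b + s))] <-
        pr[min(6, max(1, b + s))] + p / 2
    pr
  }
  po <- mean(vapply(1:6, function(b) sum(trans(b)^2), numeric(1)))
  marg <- rowMeans(vapply(1:6, trans, numeric(6)))
  pe <- sum(marg^2)
  (po - pe) / (1 - pe)
}
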