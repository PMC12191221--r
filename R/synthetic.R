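# Seeded synthetic lymph-node cohorts emulating the published group-level
# feature distributions, plus multi-reader rating panels with an
# adjacent-category noise kernel.

default_feature_params <- function() {
  # group -> feature -> (mean, sd) in mm
  list(
    benign = list(lad = c(17.2, 9.1), sad = c(7.4, 3.3),
                  ctd = c(4.5, 3.2), mtd = c(2.9, 2.4)),
    cancer = list(lad = c(17.2, 10.0), sad = c(12.0, 7.7),
                  ctd = c(11.5, 7.9), mtd = c(0.9, 1.8)),
    leukemia_lymphoma = list(lad = c(29.9, 11.7), sad = c(18.2, 7.6),
                             ctd = c(15.4, 8.4), mtd = c(2.0, 2.5)),
    melanoma_sarcoma = list(lad = c(23.3, 14.7), sad = c(15.8, 11.6),
                            ctd = c(15.8, 11.6), mtd = c(0.9, 1.9)),
    nonspecific = list(lad = c(16.6, 9.2), sad = c(10.0, 6.9),
                       ctd = c(10.1, 7.1), mtd = c(1.1, 1.6)))
}

default_vascular_mixture <- function() {
  list(benign = c(8, 36, 11, 17, 7) / 79,
       malignant = c(9, 15, 13, 60, 62) / 159)
}

#' Parameters of the synthetic-cohort generator
#'
#' Defaults reproduce the validation study's composition: per-cohort group
#' sizes, per-group feature means/SDs in mm, the empirical vascular-pattern
#' mixtures by outcome class, and the fraction of nodes with a Doppler
#' study. `grade_shift` moves malignant nodes' latent subjective grades
#' toward the malignant pole (in latent SD units); finding and clinical
#' rates are realism choices documented in the methods vignette.
#'
#' @param n_per_group Named counts for groups `benign`, `cancer`,
#'   `leukemia_lymphoma`, `melanoma_sarcoma`, `nonspecific` (missing names
#'   default to 0).
#' @param feature_params Per group, list of `(mean, sd)` pairs for `lad`,
#'   `sad`, `ctd`, `mtd`.
#' @param vascular_mixture Probability vectors over patterns 1-5 per
#'   outcome class (`benign`, `malignant`).
#' @param doppler_fraction Probability a node has a Doppler study.
#' @param grade_shift Latent-scale shift (>= 0) applied to malignant
#'   nodes' subjective grades.
#' @param clinical_flag_rate Named per-group probability that each of the
#'   six clinical-context flags is set.
#' @param finding_rates Per outcome class, named probabilities for the six
#'   architectural findings.
#' @param steatotic_rate Per outcome class, probability that a node with a
#'   visible hilum has a steatotic hilum.
#' @param seed Integer seed; every draw flows from it.
#' @return Object of class `lnrads_cohort_spec` (a named list).
#' @export
cohort_spec <- function(n_per_group = c(benign = 330, cancer = 233,
                                        leukemia_lymphoma = 93,
                                        melanoma_sarcoma = 48,
                                        nonspecific = 17),
                        feature_params = default_feature_params(),
                        vascular_mixture = default_vascular_mixture(),
                        doppler_fraction = 238 / 719,
                        grade_shift = 1.5,
                        clinical_flag_rate = c(benign = 0.03, cancer = 0.35,
                                               leukemia_lymphoma = 0.35,
                                               melanoma_sarcoma = 0.35,
                                               nonspecific = 0.35),
                        finding_rates = list(
                          benign = c(fct = 0.01, lct = 0.05,
                                     microcalcifications = 0.01,
                                     fluid_collections = 0.01,
                                     necrosis = 0.005,
                                     extracapsular_infiltration = 0),
                          malignant = c(fct = 0.30, lct = 0.15,
                                        microcalcifications = 0.10,
                                        fluid_collections = 0.05,
                                        necrosis = 0.12,
                                        extracapsular_infiltration = 0.05)),
                        steatotic_rate = c(benign = 0.25, malignant = 0.02),
                        seed = 1L) {
  groups <- c("benign", "cancer", "leukemia_lymphoma", "melanoma_sarcoma",
              "nonspecific")
  n <- stats::setNames(rep(0L, length(groups)), groups)
  n[names(n_per_group)] <- as.integer(n_per_group)
  for (v in vascular_mixture) {
    if (length(v) != 5L || any(v < 0) || abs(sum(v) - 1) > 1e-9) {
      stop("cohort_spec: vascular mixtures must be length-5 probability vectors")
    }
  }
  if (doppler_fraction < 0 || doppler_fraction > 1) {
    stop("cohort_spec: doppler_fraction must be a probability")
  }
  if (grade_shift < 0) stop("cohort_spec: grade_shift must be >= 0")
  for (g in groups[n > 0]) {
    fp <- feature_params[[g]]
    if (is.null(fp) || !all(c("lad", "sad", "ctd", "mtd") %in% names(fp))) {
      stop("cohort_spec: feature_params missing for group ", g)
    }
    if (any(vapply(fp, function(ms) ms[2] < 0 || ms[1] < 0, logical(1)))) {
      stop("cohort_spec: feature means/SDs must be non-negative")
    }
  }
  structure(list(n_per_group = n, feature_params = feature_params,
                 vascular_mixture = vascular_mixture,
                 doppler_fraction = doppler_fraction,
                 grade_shift = grade_shift,
                 clinical_flag_rate = clinical_flag_rate,
                 finding_rates = finding_rates,
                 steatotic_rate = steatotic_rate,
                 seed = as.integer(seed)),
            class = "lnrads_cohort_spec")
}

# Quantile sampler for a normal truncated below at 0 (conditional form):
# smooth in mu for fixed uniforms, which calibration exploits.
rtrunc0 <- function(u, mu, sd) {
  if (sd == 0) return(rep(max(mu, 0), length(u)))
  p0 <- stats::pnorm(0, mu, sd)
  p <- pmin(p0 + u * (1 - p0), 1 - 1e-16)
  pmax(0, stats::qnorm(p, mu, sd))
}

# Censored-at-zero normal: exact zeros encode an absent hilum.
rcens0 <- function(u, mu, sd) {
  if (sd == 0) return(rep(max(mu, 0), length(u)))
  pmax(0, stats::qnorm(u, mu, sd))
}

# Location calibration: choose mu so that the realised post-repair mean of
# `fun(mu)` matches `target`, using common random numbers. Where the target
# sits on the boundary of the reachable set (the order repairs put a hard
# ceiling on some means), optimize() settles at the bracket end giving the
# closest reachable mean.
calibrate_mu <- function(fun, target, sd) {
  if (sd == 0) return(target)
  # below -6 sd the truncation region carries no numeric mass; above
  # target + 20 sd every repair ceiling is saturated
  lower <- max(target - 20 * sd, -6 * sd)
  upper <- target + 20 * sd
  stats::optimize(function(mu) abs(mean(fun(mu)) - target),
                  lower = lower, upper = upper,
                  tol = 1e-4 * max(sd, 1))$minimum
}

# Sequentially calibrated location parameters for one group, using a
# dedicated calibration sample (fixed internal seed, set by the caller).
calibrate_group <- function(fp, u) {
  mu <- list()
  mu$sad <- calibrate_mu(function(m) rtrunc0(u[, 2], m, fp$sad[2]),
                         fp$sad[1], fp$sad[2])
  s_cal <- rtrunc0(u[, 2], mu$sad, fp$sad[2])
  mu$lad <- calibrate_mu(function(m) pmax(rtrunc0(u[, 1], m, fp$lad[2]), s_cal),
                         fp$lad[1], fp$lad[2])
  mu$ctd <- calibrate_mu(function(m) pmin(rtrunc0(u[, 3], m, fp$ctd[2]), s_cal),
                         fp$ctd[1], fp$ctd[2])
  mu$mtd <- calibrate_mu(function(m) pmin(rcens0(u[, 4], m, fp$mtd[2]), s_cal),
                         fp$mtd[1], fp$mtd[2])
  mu
}

# Morphometrics for one group from calibrated locations: sample, then
# repair the order constraints (LAD >= SAD; CTD <= SAD; MTD <= SAD).
sample_morpho <- function(n, fp, mu) {
  u <- matrix(stats::runif(4 * n), ncol = 4)
  sad <- rtrunc0(u[, 2], mu$sad, fp$sad[2])
  lad <- pmax(rtrunc0(u[, 1], mu$lad, fp$lad[2]), sad)
  ctd <- pmin(rtrunc0(u[, 3], mu$ctd, fp$ctd[2]), sad)
  mtd <- pmin(rcens0(u[, 4], mu$mtd, fp$mtd[2]), sad)
  data.frame(sad_mm = sad, lad_mm = lad, ctd_mm = ctd, mtd_mm = mtd)
}

#' Generate a synthetic lymph-node cohort
#'
#' Draws per-group morphometrics from zero-truncated normal distributions
#' whose location parameters are calibrated (common-random-number search
#' against the full sampling-plus-repair pipeline, fixed internal seed) so
#' that realised post-repair group means match the requested targets
#' despite truncation; repairs the axis-order constraints; encodes an
#' absent hilum as `mtd_mm = 0`; samples the vascular pattern for the
#' Doppler fraction from the outcome-class mixture; draws subjective
#' grades by discretising a unit-SD latent shifted by `grade_shift` for
#' malignant nodes; and attaches findings, clinical flags, histopathology
#' and cohort tags. Fully reproducible from `spec$seed`; the caller's RNG
#' state is left untouched.
#'
#' @param spec A [cohort_spec()].
#' @return Data frame in the [node_schema()] layout; every record passes
#'   [validate_nodes()].
#' @export
generate_cohort <- function(spec = cohort_spec()) {
  stopifnot(inherits(spec, "lnrads_cohort_spec"))
  if (exists(".Random.seed", envir = globalenv())) {
    old_seed <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old_seed, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()))
  }

  groups <- names(spec$n_per_group)[spec$n_per_group > 0]
  # calibration pass: fixed internal seed, independent of spec$seed
  set.seed(104729L)
  u_cal <- matrix(stats::runif(4 * 20000L), ncol = 4)
  mus <- lapply(groups, function(g) {
    calibrate_group(spec$feature_params[[g]], u_cal)
  })
  names(mus) <- groups

  set.seed(spec$seed)
  blocks <- lapply(groups, function(g) {
    n <- spec$n_per_group[[g]]
    fp <- spec$feature_params[[g]]
    malignant <- g != "benign"
    cls <- if (malignant) "malignant" else "benign"
    morpho <- sample_morpho(n, fp, mus[[g]])

    grade_mu <- 2 + if (malignant) spec$grade_shift else 0
    grade <- function() pmin(5L, pmax(1L, as.integer(round(
      stats::rnorm(n, grade_mu, 1)))))
    grades <- data.frame(shape_grade = grade(),
                         cortex_irregularity_grade = grade(),
                         echogenicity_grade = grade(),
                         inhomogeneity_grade = grade(),
                         border_grade = grade())

    has_doppler <- stats::runif(n) < spec$doppler_fraction
    vp <- rep(NA_integer_, n)
    vp[has_doppler] <- sample.int(5L, sum(has_doppler), replace = TRUE,
                                  prob = spec$vascular_mixture[[cls]])

    fr <- spec$finding_rates[[cls]]
    findings <- data.frame(
      hilum_present = morpho$mtd_mm > 0,
      steatotic_hilum = morpho$mtd_mm > 0 &
        stats::runif(n) < spec$steatotic_rate[[cls]],
      fct = stats::runif(n) < fr[["fct"]],
      lct = stats::runif(n) < fr[["lct"]],
      microcalcifications = stats::runif(n) < fr[["microcalcifications"]],
      fluid_collections = stats::runif(n) < fr[["fluid_collections"]],
      necrosis = stats::runif(n) < fr[["necrosis"]],
      extracapsular_infiltration =
        stats::runif(n) < fr[["extracapsular_infiltration"]])

    rate <- spec$clinical_flag_rate[[g]]
    clinical <- as.data.frame(stats::setNames(
      lapply(clinical_cols(), function(cc) stats::runif(n) < rate),
      clinical_cols()))

    block <- data.frame(
      node_id = sprintf("%s_%04d", g, seq_len(n)),
      region = sample(regions(), n, replace = TRUE,
                      prob = c(243, 51, 278, 147) / 719))
    block <- cbind(block, morpho, grades,
                   data.frame(vascular_pattern = vp),
                   findings, clinical)
    block$histopathology <- cls
    block$cohort <- g
    block
  })
  out <- do.call(rbind, blocks)
  rownames(out) <- NULL
  out[, node_schema()]
}

#' Perturb a base category vector into a multi-reader panel
#'
#' Each reader independently keeps each base category with probability
#' `1 - perturb_prob`; otherwise the category moves one step up or down
#' the six-level order with equal probability, reflecting at the ends
#' (a down-step from category 1 stays at 1, so a fully perturbed
#' all-1 base yields only categories 1 and 2).
#'
#' @param base Vector coercible by [lnrads_factor()].
#' @param n_readers Number of readers.
#' @param perturb_prob Per-item perturbation probability in `[0, 1]`.
#' @param seed Integer seed; the caller's RNG state is left untouched.
#' @return Data frame with one ordered-factor column per reader
#'   (`reader_1`, `reader_2`, ...).
#' @export
generate_reader_panel <- function(base, n_readers = 3, perturb_prob = 0.2,
                                  seed = 1L) {
  if (length(base) == 0L) stop("generate_reader_panel: empty base")
  if (perturb_prob < 0 || perturb_prob > 1) {
    stop("generate_reader_panel: perturb_prob must be in [0, 1]")
  }
  base_i <- as.integer(lnrads_factor(base))
  if (exists(".Random.seed", envir = globalenv())) {
    old_seed <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old_seed, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  n <- length(base_i)
  cols <- lapply(seq_len(n_readers), function(r) {
    move <- stats::runif(n) < perturb_prob
    step <- sample(c(-1L, 1L), n, replace = TRUE)
    idx <- ifelse(move, pmin(6L, pmax(1L, base_i + step)), base_i)
    lnrads_factor(lnrads_levels()[idx])
  })
  stats::setNames(as.data.frame(cols), paste0("reader_", seq_len(n_readers)))
}
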