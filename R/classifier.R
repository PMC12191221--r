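# The LN-RADS rule cascade: configurable thresholds, the malignant-feature
# list, and the deterministic category assignment.

#' Numeric cutoffs of the LN-RADS rule cascade
#'
#' Every threshold used by [classify_nodes()] lives here so the cascade is
#' fully configurable. Comparisons follow the scale's wording: "over X mm"
#' is strict (`>`), "maximum X mm" is inclusive (`<=`), and a node is oval
#' when `s_over_l < oval_s_over_l_max` (equivalently L/S > 2 at the
#' default).
#'
#' @param sad_normal_max_mm Largest short axis still "not enlarged" (mm).
#' @param sad_enlarged_min_mm Enlargement cutoff for category 5: enlarged
#'   iff `sad_mm > sad_enlarged_min_mm`. Default 9 mm, the optimal
#'   discriminating short-axis cutoff, rather than the conventional 10 mm.
#' @param ctd_thin_max_mm Largest "thin, regular" cortex (mm, inclusive).
#' @param ctd_4b_min_mm Cortical thickening beyond this (strict) combined
#'   with irregularity is a high-risk feature.
#' @param ctd_5_min_mm Cortical thickening typical of category 5 (strict);
#'   retained as scale metadata, the cascade reaches 5 through the
#'   high-risk feature count.
#' @param oval_s_over_l_max Roundness cutoff: oval iff `s_over_l` is
#'   strictly below this value.
#' @param high_risk_count_for_5 Number of malignant features that, together
#'   with short-axis enlargement, forces category 5.
#' @return Object of class `lnrads_rule_config` (a named list).
#' @export
rule_config <- function(sad_normal_max_mm = 7,
                        sad_enlarged_min_mm = 9,
                        ctd_thin_max_mm = 3,
                        ctd_4b_min_mm = 4,
                        ctd_5_min_mm = 6,
                        oval_s_over_l_max = 0.5,
                        high_risk_count_for_5 = 2) {
  cfg <- list(sad_normal_max_mm = sad_normal_max_mm,
              sad_enlarged_min_mm = sad_enlarged_min_mm,
              ctd_thin_max_mm = ctd_thin_max_mm,
              ctd_4b_min_mm = ctd_4b_min_mm,
              ctd_5_min_mm = ctd_5_min_mm,
              oval_s_over_l_max = oval_s_over_l_max,
              high_risk_count_for_5 = high_risk_count_for_5)
  if (any(vapply(cfg, function(x) !is.numeric(x) || length(x) != 1L ||
                   is.na(x) || x <= 0, logical(1)))) {
    stop("rule_config: all thresholds must be single positive numbers")
  }
  if (!(cfg$ctd_thin_max_mm < cfg$ctd_4b_min_mm &&
        cfg$ctd_4b_min_mm < cfg$ctd_5_min_mm)) {
    stop("rule_config: need ctd_thin_max_mm < ctd_4b_min_mm < ctd_5_min_mm")
  }
  structure(cfg, class = "lnrads_rule_config")
}

#' Identifiers of the high-risk ("malignant") feature list
#'
#' @return Character vector of the ten feature identifiers scanned by
#'   [malignant_features()].
#' @export
malignant_feature_ids <- function() {
  c("CTD_OVER_4B_WITH_IRREGULARITY", "FCT", "NO_HILUM", "ROUND",
    "DEEP_HYPOECHOIC", "MICROCALCIFICATIONS", "FLUID", "NECROSIS",
    "ABNORMAL_VASCULARITY", "BLURRED_MARGINS")
}

# Internal: logical matrix (nodes x features) of high-risk feature presence.
malignant_feature_matrix <- function(nodes, config = rule_config()) {
  nodes <- add_ratios(nodes)
  vp <- nodes$vascular_pattern
  m <- cbind(
    CTD_OVER_4B_WITH_IRREGULARITY =
      nodes$ctd_mm > config$ctd_4b_min_mm &
      nodes$cortex_irregularity_grade >= 3,
    FCT = nodes$fct,
    NO_HILUM = nodes$mtd_mm == 0,
    ROUND = nodes$s_over_l >= config$oval_s_over_l_max,
    DEEP_HYPOECHOIC = nodes$echogenicity_grade >= 4,
    MICROCALCIFICATIONS = nodes$microcalcifications,
    FLUID = nodes$fluid_collections,
    NECROSIS = nodes$necrosis,
    ABNORMAL_VASCULARITY = !is.na(vp) & vp >= 4,
    BLURRED_MARGINS = nodes$border_grade >= 4)
  m
}

#' High-risk features present on each node
#'
#' Evaluates the fixed malignant-feature list: markedly thickened and
#' irregular cortex, focal cortical thickening, absent hilum, round shape,
#' deep hypoechogenicity (toward the "black hole sign"),
#' microcalcifications, fluid collections, necrosis, peripheral or chaotic
#' vascularization, and blurred margins. An absent Doppler study
#' contributes nothing.
#'
#' @param nodes Data frame in the [node_schema()] layout.
#' @param config A [rule_config()].
#' @return List (one element per node) of character vectors drawn from
#'   [malignant_feature_ids()].
#' @export
malignant_features <- function(nodes, config = rule_config()) {
  m <- malignant_feature_matrix(nodes, config)
  ids <- colnames(m)
  lapply(seq_len(nrow(m)), function(i) ids[m[i, ]])
}

#' Study-estimated malignancy risk label for each category
#'
#' Descriptive metadata attached to classifications: the malignancy risk
#' observed per category in the validation cohort.
#'
#' @param category Vector coercible by [lnrads_factor()].
#' @return Character vector of risk labels ("0%", "0%", "2%", "31%",
#'   "77%", "97%").
#' @export
risk_band <- function(category) {
  bands <- c("1" = "0%", "2" = "0%", "3" = "2%",
             "4a" = "31%", "4b" = "77%", "5" = "97%")
  unname(bands[as.character(lnrads_factor(category))])
}

#' Collapse LN-RADS categories to a positive/negative test
#'
#' The statistical scheme treats 4a as negative (its observed risk is
#' below one half), so positives are 4b and 5; the management scheme
#' flags everything that warrants workup, so positives are 4a, 4b and 5.
#'
#' @param category Vector coercible by [lnrads_factor()].
#' @param scheme `"statistical"` or `"management"`.
#' @return Factor with levels `negative`, `positive`.
#' @export
binarize <- function(category, scheme = c("statistical", "management")) {
  scheme <- match.arg(scheme)
  cat <- lnrads_factor(category)
  pos <- if (scheme == "statistical") c("4b", "5") else c("4a", "4b", "5")
  factor(ifelse(as.character(cat) %in% pos, "positive", "negative"),
         levels = c("negative", "positive"))
}

#' Assign LN-RADS categories by the deterministic rule cascade
#'
#' Rules are evaluated malignant-first and the first match decides:
#' \describe{
#'   \item{R5_EXTRACAPSULAR}{extracapsular infiltration is an unequivocal
#'     invasion sign and forces category 5;}
#'   \item{R5_ENLARGED_HIGH_RISK}{short-axis enlargement together with at
#'     least `high_risk_count_for_5` malignant features gives 5;}
#'   \item{R4B_HIGH_RISK}{any malignant feature gives 4b;}
#'   \item{R1_NORMAL}{small, oval, thin regular cortex, normal
#'     echogenicity, smooth margins, visible hilum, clean architecture,
#'     hilar-type or absent Doppler, no clinical context;}
#'   \item{R2_STEATOTIC}{steatotic hilum with thin regular cortex and clean
#'     architecture, any size;}
#'   \item{R3_REACTIVE}{cortex thickened beyond `ctd_thin_max_mm` but
#'     regular, oval, preserved medulla, at most moderate hypoechogenicity,
#'     sharp margins, clean architecture (local cortical thickening
#'     tolerated), no clinical context;}
#'   \item{R4A_FALLBACK}{everything else is 4a — better check than miss.}
#' }
#' Any clinical-context flag blocks the benign screens, so a reactive-looking
#' node with, say, an active regional neoplasm lands in 4a (never higher on
#' clinical grounds alone).
#'
#' @param nodes Data frame in the [node_schema()] layout.
#' @param config A [rule_config()].
#' @return Data frame with one row per node: `node_id`, `category`
#'   (ordered factor), `rule` (identifier of the deciding rule),
#'   `n_malignant_features`, `malignant_features` (comma-separated ids),
#'   `triggered_rules` (list column: deciding rule followed by the feature
#'   ids), `risk_band`, `positive_statistical`, `positive_management`.
#' @examples
#' node <- synthetic_cohort(cohort_spec(n_per_group = c(benign = 1), seed = 1))
#' classify_nodes(node)[, c("category", "rule")]
#' @export
classify_nodes <- function(nodes, config = rule_config()) {
  if (!inherits(config, "lnrads_rule_config")) {
    config <- do.call(rule_config, as.list(config))
  }
  n <- nrow(nodes)
  nodes <- add_ratios(nodes)
  m <- malignant_feature_matrix(nodes, config)
  n_m <- rowSums(m)
  vp <- nodes$vascular_pattern

  clinical_any <- Reduce(`|`, lapply(clinical_cols(), function(cc) nodes[[cc]]))
  no_findings <- !nodes$fct & !nodes$lct & !nodes$microcalcifications &
    !nodes$fluid_collections & !nodes$necrosis
  vascular_benign <- is.na(vp) | vp <= 3
  oval <- nodes$s_over_l < config$oval_s_over_l_max

  r5a <- nodes$extracapsular_infiltration
  r5b <- nodes$sad_mm > config$sad_enlarged_min_mm &
    n_m >= config$high_risk_count_for_5
  r4b <- n_m >= 1
  r1 <- nodes$sad_mm <= config$sad_normal_max_mm & oval &
    nodes$ctd_mm <= config$ctd_thin_max_mm &
    nodes$cortex_irregularity_grade <= 2 &
    nodes$echogenicity_grade <= 2 & nodes$border_grade <= 2 &
    nodes$hilum_present & no_findings & vascular_benign & !clinical_any
  r2 <- nodes$ctd_mm <= config$ctd_thin_max_mm &
    nodes$cortex_irregularity_grade <= 2 & nodes$steatotic_hilum &
    no_findings & nodes$border_grade <= 2 & vascular_benign & !clinical_any
  r3 <- nodes$ctd_mm > config$ctd_thin_max_mm &
    nodes$cortex_irregularity_grade <= 2 & oval & nodes$hilum_present &
    nodes$echogenicity_grade <= 3 & nodes$border_grade <= 2 & !nodes$fct &
    !nodes$microcalcifications & !nodes$fluid_collections & !nodes$necrosis &
    vascular_benign & !clinical_any

  rule <- rep("R4A_FALLBACK", n)
  category <- rep("4a", n)
  assign_rule <- function(sel, id, cat) {
    sel <- sel & rule == "R4A_FALLBACK" & category == "4a" & !assigned
    rule[sel] <<- id; category[sel] <<- cat; assigned[sel] <<- TRUE
  }
  assigned <- rep(FALSE, n)
  assign_rule(r5a, "R5_EXTRACAPSULAR", "5")
  assign_rule(r5b, "R5_ENLARGED_HIGH_RISK", "5")
  assign_rule(r4b, "R4B_HIGH_RISK", "4b")
  assign_rule(r1, "R1_NORMAL", "1")
  assign_rule(r2, "R2_STEATOTIC", "2")
  assign_rule(r3, "R3_REACTIVE", "3")

  feats <- malignant_features(nodes, config)
  cat_f <- lnrads_factor(category)
  out <- data.frame(node_id = as.character(nodes$node_id),
                    stringsAsFactors = FALSE)
  out$category <- cat_f
  out$rule <- rule
  out$n_malignant_features <- as.integer(n_m)
  out$malignant_features <- vapply(feats, paste, character(1), collapse = ",")
  out$triggered_rules <- I(mapply(function(r, f) c(r, f), rule, feats,
                                  SIMPLIFY = FALSE, USE.NAMES = FALSE))
  out$risk_band <- risk_band(cat_f)
  out$positive_statistical <- binarize(cat_f, "statistical") == "positive"
  out$positive_management <- binarize(cat_f, "management") == "positive"
  out
}
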