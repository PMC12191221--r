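# Data model shared by all stages: the LN-RADS category scale, the tabular
# lymph-node record schema, derived ratios, and record validation.

#' The six LN-RADS categories in ascending order of suspicion
#'
#' @return Character vector `c("1", "2", "3", "4a", "4b", "5")`.
#' @export
lnrads_levels <- function() c("1", "2", "3", "4a", "4b", "5")

#' Coerce to an ordered LN-RADS category factor
#'
#' @param x Character, factor or numeric-like vector of category labels.
#' @return Ordered factor with levels `1 < 2 < 3 < 4a < 4b < 5`.
#' @export
lnrads_factor <- function(x) {
  x <- as.character(x)
  bad <- !is.na(x) & !(x %in% lnrads_levels())
  if (any(bad)) {
    stop("unknown LN-RADS category label(s): ",
         paste(unique(x[bad]), collapse = ", "))
  }
  factor(x, levels = lnrads_levels(), ordered = TRUE)
}

# Column groups of the CSV node schema. Order matters for writers.
morpho_cols <- function() c("sad_mm", "lad_mm", "ctd_mm", "mtd_mm")

grade_cols <- function() {
  c("shape_grade", "cortex_irregularity_grade", "echogenicity_grade",
    "inhomogeneity_grade", "border_grade")
}

finding_cols <- function() {
  c("hilum_present", "steatotic_hilum", "fct", "lct", "microcalcifications",
    "fluid_collections", "necrosis", "extracapsular_infiltration")
}

clinical_cols <- function() {
  c("oncological_history", "hematological_history", "active_regional_neoplasm",
    "elevated_or_rising_markers", "other_suspicious_regional_ln",
    "systemic_symptoms")
}

#' Column names of the lymph-node CSV schema, in canonical order
#'
#' @return Character vector of the 28 schema columns.
#' @export
node_schema <- function() {
  c("node_id", "region", morpho_cols(), grade_cols(), "vascular_pattern",
    finding_cols(), clinical_cols(), "histopathology", "cohort")
}

regions <- function() c("neck", "periclavicular", "axilla", "inguinal")

cohorts_malignant <- function() {
  c("cancer", "leukemia_lymphoma", "melanoma_sarcoma", "nonspecific")
}

#' Derived shape and hilum ratios
#'
#' Computes the two dimensionless ratios used throughout the scale:
#' `s_over_l = sad_mm / lad_mm` (roundness; 1 = perfectly round) and
#' `medulla_fraction = mtd_mm / (mtd_mm + ctd_mm)` (how much of the
#' cortex-plus-medulla thickness the medulla occupies; 0 encodes an absent
#' hilum). Values are exact, never rounded.
#'
#' @param sad_mm Short-axis diameter in mm, or a data frame carrying the
#'   four morphometric columns (then the remaining arguments are ignored).
#' @param lad_mm Long-axis diameter in mm.
#' @param ctd_mm Maximal cortical thickness in mm.
#' @param mtd_mm Medullary (hilar) thickness in mm; 0 when no hilum.
#' @return Data frame with columns `s_over_l` and `medulla_fraction`.
#' @examples
#' derive_ratios(5, 10, 2, 2)   # 0.5 and 0.5
#' derive_ratios(8, 8, 8, 0)    # 1.0 and 0.0 (round node, absent hilum)
#' @export
derive_ratios <- function(sad_mm, lad_mm = NULL, ctd_mm = NULL, mtd_mm = NULL) {
  if (is.data.frame(sad_mm)) {
    df <- sad_mm
    sad_mm <- df$sad_mm; lad_mm <- df$lad_mm
    ctd_mm <- df$ctd_mm; mtd_mm <- df$mtd_mm
  }
  if (any(lad_mm == 0)) {
    stop("degenerate input: lad_mm = 0")
  }
  if (any(ctd_mm + mtd_mm == 0)) {
    stop("degenerate input: ctd_mm + mtd_mm = 0 (medulla fraction undefined)")
  }
  data.frame(s_over_l = sad_mm / lad_mm,
             medulla_fraction = mtd_mm / (mtd_mm + ctd_mm))
}

# Internal: append ratio columns to a node data frame.
add_ratios <- function(nodes) {
  r <- derive_ratios(nodes)
  nodes$s_over_l <- r$s_over_l
  nodes$medulla_fraction <- r$medulla_fraction
  nodes
}

#' Validate lymph-node records against the data-model invariants
#'
#' Checks every structural invariant of the record schema and returns the
#' violations found instead of raising: positive axes with `lad >= sad`,
#' cortical/medullary thickness bounded by the short axis, integer grades in
#' 1..5 (the vascular pattern may be absent when Doppler was not performed),
#' a steatotic hilum implying a visible hilum, agreement between
#' `hilum_present` and the canonical `mtd_mm = 0` encoding of a missing
#' hilum, and consistency of cohort tags with the histopathology label.
#'
#' @param nodes Data frame in the [node_schema()] layout.
#' @return Data frame with columns `row`, `node_id`, `field`, `violation`;
#'   zero rows when every record is consistent.
#' @export
validate_nodes <- function(nodes) {
  out <- list()
  hit <- function(rows, field, msg) {
    if (any(rows)) {
      out[[length(out) + 1L]] <<- data.frame(
        row = which(rows),
        node_id = as.character(nodes$node_id[rows]),
        field = field, violation = msg)
    }
  }
  num_bad <- function(x) is.na(x) | !is.finite(x)

  hit(num_bad(nodes$sad_mm) | nodes$sad_mm <= 0, "sad_mm",
      "short-axis diameter must be a positive length")
  hit(num_bad(nodes$lad_mm) | nodes$lad_mm <= 0, "lad_mm",
      "long-axis diameter must be a positive length")
  hit(num_bad(nodes$ctd_mm) | nodes$ctd_mm < 0, "ctd_mm",
      "cortical thickness must be a non-negative length")
  hit(num_bad(nodes$mtd_mm) | nodes$mtd_mm < 0, "mtd_mm",
      "medullary thickness must be a non-negative length")
  ok <- !num_bad(nodes$sad_mm) & !num_bad(nodes$lad_mm)
  hit(ok & nodes$lad_mm < nodes$sad_mm, "lad_mm",
      "axis order violated: lad_mm must be >= sad_mm")
  ok <- !num_bad(nodes$sad_mm) & !num_bad(nodes$ctd_mm)
  hit(ok & nodes$ctd_mm > nodes$sad_mm, "ctd_mm",
      "cortical thickness exceeds short-axis diameter")
  ok <- !num_bad(nodes$sad_mm) & !num_bad(nodes$mtd_mm)
  hit(ok & nodes$mtd_mm > nodes$sad_mm, "mtd_mm",
      "medullary thickness exceeds short-axis diameter")

  for (g in grade_cols()) {
    x <- nodes[[g]]
    hit(is.na(x) | x != round(x) | x < 1 | x > 5, g,
        "grade must be an integer in 1..5")
  }
  vp <- nodes$vascular_pattern
  hit(!is.na(vp) & (vp != round(vp) | vp < 1 | vp > 5), "vascular_pattern",
      "vascular pattern, when present, must be an integer in 1..5")

  hit(nodes$steatotic_hilum & !nodes$hilum_present, "steatotic_hilum",
      "steatotic hilum requires hilum_present")
  ok <- !num_bad(nodes$mtd_mm)
  hit(ok & !nodes$hilum_present & nodes$mtd_mm > 0, "hilum_present",
      "hilum/MTD consistency: hilum_present = FALSE requires mtd_mm = 0")
  hit(ok & nodes$hilum_present & nodes$mtd_mm == 0, "hilum_present",
      "hilum/MTD consistency: hilum_present = TRUE requires mtd_mm > 0")

  hit(!is.na(nodes$region) & !(nodes$region %in% regions()), "region",
      "unknown region")
  hp <- as.character(nodes$histopathology)
  hit(!is.na(hp) & !(hp %in% c("benign", "malignant")), "histopathology",
      "histopathology must be benign or malignant when present")
  ch <- as.character(nodes$cohort)
  hit(!is.na(ch) & !(ch %in% c("benign", cohorts_malignant())), "cohort",
      "unknown cohort tag")
  hit(!is.na(ch) & ch == "benign" & (is.na(hp) | hp != "benign"), "cohort",
      "cohort = benign requires histopathology = benign")
  hit(!is.na(ch) & ch %in% cohorts_malignant() &
        (is.na(hp) | hp != "malignant"), "cohort",
      "a malignant cohort tag requires histopathology = malignant")

  if (length(out) == 0L) {
    return(data.frame(row = integer(), node_id = character(),
                      field = character(), violation = character()))
  }
  res <- do.call(rbind, out)
  res <- res[order(res$row, res$field), , drop = FALSE]
  rownames(res) <- NULL
  res
}
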