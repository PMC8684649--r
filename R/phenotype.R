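# MUNO phenotype classification.
#
# Four metabolic-syndrome components; MUNO = non-obese (BMI < 25 kg/m2)
# with two or more components, MHNO = non-obese with at most one.
# Medication use is sufficient for its component regardless of the measured
# value (e.g. an antihypertensive user with SBP 110 still scores the BP
# component).

#' Metabolic-syndrome component flags
#'
#' The four components, with thresholds applied exactly as stated
#' (inclusive where marked):
#' * BP: SBP >= 130 mmHg or DBP >= 85 mmHg, or antihypertensive use;
#' * TG: TG >= 1.7 mmol/L;
#' * HDL: HDL < 1.0 mmol/L (men) / < 1.3 mmol/L (women), or lipid-lowering
#'   drug use (lipid-lowering use does not feed the TG component);
#' * FPG: FPG >= 5.6 mmol/L, or antidiabetic treatment.
#'
#' @param cohort A cohort tibble with complete analysis fields.
#' @return A tibble with `id`, the four logical component flags, and
#'   `component_count` (0-4).
#' @export
mets_components <- function(cohort) {
  need <- c("id", "sex", "sbp", "dbp", "tg", "hdl", "fpg",
            "on_antihypertensive", "on_antidiabetic", "on_lipid_lowering")
  for (col in need) {
    if (!col %in% names(cohort)) stop("missing field: ", col)
    bad <- is.na(cohort[[col]])
    if (any(bad)) {
      stop("missing ", col, " for id(s): ",
           paste(head(cohort$id[bad], 5), collapse = ", "))
    }
  }
  check_sex(cohort$sex)
  bp  <- cohort$sbp >= 130 | cohort$dbp >= 85 | cohort$on_antihypertensive
  tgc <- cohort$tg >= 1.7
  hdl <- ifelse(cohort$sex == "male", cohort$hdl < 1.0, cohort$hdl < 1.3) |
    cohort$on_lipid_lowering
  fpg <- cohort$fpg >= 5.6 | cohort$on_antidiabetic
  tibble::tibble(
    id = cohort$id,
    bp_component = bp, tg_component = tgc,
    hdl_component = hdl, fpg_component = fpg,
    component_count = as.integer(bp) + as.integer(tgc) +
      as.integer(hdl) + as.integer(fpg)
  )
}

#' Phenotype label from BMI and component count
#'
#' `MUNO` if BMI < 25 and count >= 2 (the count-2 boundary is MUNO),
#' `MHNO` if BMI < 25 and count <= 1, `not_applicable` if BMI >= 25.
#'
#' @param cohort A cohort tibble (`height`, `weight` used for BMI).
#' @param components Output of [mets_components()]; computed if omitted.
#' @return A factor with levels `MHNO`, `MUNO`, `not_applicable`.
#' @export
classify_phenotype <- function(cohort, components = mets_components(cohort)) {
  stopifnot(identical(cohort$id, components$id))
  bmi <- compute_bmi(cohort$weight, cohort$height)
  label <- ifelse(bmi >= 25, "not_applicable",
                  ifelse(components$component_count >= 2, "MUNO", "MHNO"))
  factor(label, levels = c("MHNO", "MUNO", "not_applicable"))
}

#' Classify a cohort: indices, components and phenotype in one table
#'
#' @param cohort A cohort tibble (typically after [apply_eligibility()]).
#' @return The cohort with the seven-index panel, the component flags and
#'   counts, and a `label` factor appended.
#' @export
classify_cohort <- function(cohort) {
  panel <- compute_panel(cohort)
  comps <- mets_components(cohort)
  out <- cbind(tibble::as_tibble(cohort),
               panel[, setdiff(names(panel), c("id", "wc"))],
               comps[, setdiff(names(comps), "id")])
  out$label <- classify_phenotype(cohort, comps)
  as_cohort(out, provenance = attr(cohort, "provenance"))
}

#' MUNO prevalence among non-obese records
#'
#' @param x Either a factor/character vector of phenotype labels or a data
#'   frame with a `label` column (e.g. from [classify_cohort()]).
#' @return A list with `n_total` (MUNO + MHNO), `n_muno`, `n_mhno`, and
#'   `pct_muno` (percent, one decimal).
#' @export
phenotype_prevalence <- function(x) {
  label <- if (is.data.frame(x)) x$label else x
  if (length(label) == 0) stop("empty cohort")
  n_muno <- sum(label == "MUNO")
  n_mhno <- sum(label == "MHNO")
  n_total <- n_muno + n_mhno
  if (n_total == 0) stop("no non-obese records to summarise")
  list(n_total = n_total, n_muno = n_muno, n_mhno = n_mhno,
       pct_muno = round(100 * n_muno / n_total, 1))
}
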