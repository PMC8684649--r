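# The seven adiposity indices.
#
# All functions are vectorised and validate their domains; values are kept
# in double precision with no rounding (presentation layers round).

check_positive <- function(..., .names = NULL) {
  args <- list(...)
  names(args) <- .names %||% names(args)
  for (nm in names(args)) {
    bad <- which(args[[nm]] <= 0)
    if (length(bad) > 0) {
      stop("non-positive ", nm, " at position(s) ",
           paste(head(bad, 5), collapse = ", "), call. = FALSE)
    }
  }
  invisible(TRUE)
}

check_sex <- function(sex) {
  if (any(is.na(sex)) || !all(sex %in% c("male", "female"))) {
    stop("sex must be 'male' or 'female'", call. = FALSE)
  }
  invisible(TRUE)
}

#' Body mass index
#'
#' @param weight Weight in kg.
#' @param height Height in metres.
#' @return BMI in kg/m2.
#' @export
compute_bmi <- function(weight, height) {
  check_positive(weight = weight, height = height)
  weight / height^2
}

#' Waist-to-height ratio
#'
#' WC and height are brought to the same unit before dividing.
#'
#' @param wc Waist circumference in cm.
#' @param height Height in metres.
#' @return Dimensionless ratio.
#' @export
compute_whtr <- function(wc, height) {
  check_positive(wc = wc, height = height)
  wc / (height * 100)
}

#' Lipid accumulation product
#'
#' `(WC - 65) x TG` for men and `(WC - 58) x TG` for women. The value is
#' returned unmodified even when WC is at or below the sex anchor (LAP <= 0
#' is possible); rank-based downstream analyses are unaffected by sign.
#'
#' @param sex `"male"` or `"female"`.
#' @param wc Waist circumference in cm.
#' @param tg Triglycerides in mmol/L.
#' @return LAP in cm.mmol/L.
#' @export
compute_lap <- function(sex, wc, tg) {
  check_sex(sex)
  check_positive(wc = wc, tg = tg)
  anchor <- ifelse(sex == "male", 65, 58)
  (wc - anchor) * tg
}

#' Visceral adiposity index
#'
#' Sex-specific product of a WC/BMI ratio, a TG ratio and an HDL ratio:
#' men `WC/(39.68 + 1.88 BMI) * TG/1.03 * 1.31/HDL`, women
#' `WC/(36.58 + 1.89 BMI) * TG/0.81 * 1.52/HDL`.
#'
#' @param sex `"male"` or `"female"`.
#' @param wc Waist circumference in cm.
#' @param bmi BMI in kg/m2.
#' @param tg Triglycerides in mmol/L.
#' @param hdl HDL cholesterol in mmol/L.
#' @return Dimensionless index.
#' @export
compute_vai <- function(sex, wc, bmi, tg, hdl) {
  check_sex(sex)
  check_positive(wc = wc, bmi = bmi, tg = tg, hdl = hdl)
  ifelse(sex == "male",
         wc / (39.68 + 1.88 * bmi) * tg / 1.03 * 1.31 / hdl,
         wc / (36.58 + 1.89 * bmi) * tg / 0.81 * 1.52 / hdl)
}

#' Chinese visceral adiposity index
#'
#' Sex-specific linear score in age, BMI, WC, log10 TG and HDL:
#' men `-267.93 + 0.68 age + 0.03 BMI + 4.00 WC + 22.00 log10(TG)
#' - 16.32 HDL`; women `-187.32 + 1.71 age + 4.23 BMI + 1.12 WC
#' + 39.76 log10(TG) - 11.66 HDL`. The men's BMI coefficient (0.03) is
#' strikingly smaller than the women's (4.23); the printed constants are
#' used as-is. The score is unbounded and can be negative.
#'
#' @param sex `"male"` or `"female"`.
#' @param age Age in years.
#' @param bmi BMI in kg/m2.
#' @param wc Waist circumference in cm.
#' @param tg Triglycerides in mmol/L (must be positive: log10 argument).
#' @param hdl HDL cholesterol in mmol/L.
#' @return Dimensionless score.
#' @export
compute_cvai <- function(sex, age, bmi, wc, tg, hdl) {
  check_sex(sex)
  check_positive(age = age, bmi = bmi, wc = wc, tg = tg, hdl = hdl)
  ifelse(sex == "male",
         -267.93 + 0.68 * age + 0.03 * bmi + 4.00 * wc +
           22.00 * log10(tg) - 16.32 * hdl,
         -187.32 + 1.71 * age + 4.23 * bmi + 1.12 * wc +
           39.76 * log10(tg) - 11.66 * hdl)
}

#' A body shape index
#'
#' `WC(m) / (BMI^(2/3) * height^(1/2))`; WC is converted from cm to metres
#' internally (the only place the package changes the WC unit).
#'
#' @param wc Waist circumference in cm.
#' @param bmi BMI in kg/m2.
#' @param height Height in metres.
#' @return ABSI score (around 0.08 in adults).
#' @export
compute_absi <- function(wc, bmi, height) {
  check_positive(wc = wc, bmi = bmi, height = height)
  (wc / 100) / (bmi^(2 / 3) * sqrt(height))
}

#' Compute the full seven-index panel for a cohort
#'
#' BMI is computed first and reused by VAI, CVAI and ABSI; WC is passed
#' through unchanged. The per-cohort count of non-positive LAP values is
#' logged.
#'
#' @param cohort A cohort tibble (or any data frame with the mandatory
#'   fields of [cohort_dictionary()]).
#' @return A tibble with columns `id`, `bmi`, `wc`, `whtr`, `vai`, `cvai`,
#'   `absi`, `lap`.
#' @export
compute_panel <- function(cohort) {
  need <- c("id", "sex", "age", "height", "weight", "wc", "tg", "hdl")
  miss <- setdiff(need, names(cohort))
  if (length(miss) > 0) stop("missing field(s): ", paste(miss, collapse = ", "))
  with_id <- function(expr) {
    tryCatch(expr, error = function(e) {
      stop("index computation failed (", conditionMessage(e), ")",
           call. = FALSE)
    })
  }
  bmi <- with_id(compute_bmi(cohort$weight, cohort$height))
  panel <- tibble::tibble(
    id   = cohort$id,
    bmi  = bmi,
    wc   = cohort$wc,
    whtr = with_id(compute_whtr(cohort$wc, cohort$height)),
    vai  = with_id(compute_vai(cohort$sex, cohort$wc, bmi, cohort$tg, cohort$hdl)),
    cvai = with_id(compute_cvai(cohort$sex, cohort$age, bmi, cohort$wc,
                                cohort$tg, cohort$hdl)),
    absi = with_id(compute_absi(cohort$wc, bmi, cohort$height)),
    lap  = with_id(compute_lap(cohort$sex, cohort$wc, cohort$tg))
  )
  n_nonpos <- sum(panel$lap <= 0)
  if (n_nonpos > 0) {
    muno_log("compute_panel: %d record(s) with non-positive LAP retained",
             n_nonpos)
  }
  panel
}
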