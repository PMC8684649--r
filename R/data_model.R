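# Patient data model: column dictionary, CSV I/O, validation, eligibility.
#
# Canonical units are fixed once for the whole package: height in metres,
# weight in kg, waist circumference (wc) in centimetres, blood pressure in
# mmHg, all labs (fpg, tg, hdl, ldl, tc) in mmol/L, dialysis vintage in
# months. Only the ABSI formula converts WC to metres, internally.

#' Column dictionary for a patient cohort
#'
#' Mandatory and optional columns of a cohort table, with the units the
#' package assumes. Header matching in [read_cohort()] is case-insensitive.
#'
#' @return A list with character vectors `mandatory`, `optional`,
#'   `analysis` (numeric fields required for complete-case analysis),
#'   `flags` (logical fields) and `numeric`.
#' @export
cohort_dictionary <- function() {
  flags <- c("on_antihypertensive", "on_antidiabetic", "on_lipid_lowering",
             "smoker_history", "education_ge_junior_high")
  numeric <- c("age", "height", "weight", "wc", "sbp", "dbp",
               "fpg", "tg", "hdl", "ldl", "tc", "vintage_months")
  list(
    mandatory = c("id", "age", "sex", "height", "weight", "wc", "sbp", "dbp",
                  "fpg", "tg", "hdl", flags, "vintage_months"),
    optional  = c("ldl", "tc"),
    canonical = c("id", "age", "sex", "height", "weight", "wc", "sbp", "dbp",
                  "fpg", "tg", "hdl", "ldl", "tc", flags, "vintage_months"),
    analysis  = c("height", "weight", "wc", "sbp", "dbp", "fpg", "tg", "hdl"),
    flags     = flags,
    numeric   = numeric
  )
}

# per-row invariant violations; returns character vector of messages ("" = ok)
record_violations <- function(df) {
  msg <- rep("", nrow(df))
  add <- function(bad, what) {
    bad[is.na(bad)] <- FALSE
    msg[bad] <<- ifelse(msg[bad] == "", what, paste(msg[bad], what, sep = "; "))
  }
  add(!(df$height > 0.5 & df$height < 2.5), "height outside (0.5, 2.5) m")
  add(!(df$wc > 30 & df$wc < 200), "wc outside (30, 200) cm")
  add(!(df$age >= 18 & df$age <= 120), "age outside [18, 120]")
  for (lab in c("weight", "fpg", "tg", "hdl", "ldl", "tc")) {
    if (lab %in% names(df)) add(df[[lab]] <= 0, paste(lab, "<= 0"))
  }
  add(!(df$sbp > 0) | !(df$dbp > 0), "non-positive blood pressure")
  add(!(df$vintage_months >= 0), "negative vintage")
  add(is.na(df$sex) | !(df$sex %in% c("male", "female")),
      "sex not one of male/female")
  for (fl in cohort_dictionary()$flags) {
    add(is.na(df[[fl]]), paste(fl, "missing"))
  }
  add(is.na(df$age), "age missing")
  add(is.na(df$vintage_months), "vintage_months missing")
  msg
}

parse_flag <- function(x) {
  x <- tolower(trimws(as.character(x)))
  out <- rep(NA, length(x))
  out[x %in% c("true", "t", "1", "yes", "y")] <- TRUE
  out[x %in% c("false", "f", "0", "no", "n")] <- FALSE
  out
}

as_cohort <- function(df, provenance = NULL) {
  df <- tibble::as_tibble(df)
  class(df) <- unique(c("muno_cohort", class(df)))
  attr(df, "provenance") <- provenance
  df
}

#' Read a patient cohort from CSV
#'
#' Parses a CSV file against the [cohort_dictionary()] (case-insensitive
#' headers), coerces types, and checks the record invariants. Under
#' `strict = TRUE` any malformed or invariant-violating row is an error
#' naming the row id; under `strict = FALSE` such rows are dropped and the
#' exclusion count is logged. `NA` is permitted only in the analysis labs
#' and the optional lipid fields (`ldl`, `tc`); those records are retained
#' here and removed later by [apply_eligibility()] (complete-case analysis).
#'
#' @param path Path to a CSV file.
#' @param strict Error on bad rows (`TRUE`, default) or drop them.
#' @return A `muno_cohort` tibble; dropped-row count is available via
#'   `attr(x, "n_dropped")`.
#' @export
read_cohort <- function(path, strict = TRUE) {
  if (!file.exists(path)) stop("cohort file not found: ", path)
  raw <- utils::read.csv(path, colClasses = "character",
                         check.names = FALSE, strip.white = TRUE)
  names(raw) <- tolower(trimws(names(raw)))
  dict <- cohort_dictionary()
  missing_cols <- setdiff(dict$mandatory, names(raw))
  if (length(missing_cols) > 0) {
    stop("missing mandatory column(s): ", paste(missing_cols, collapse = ", "))
  }
  raw <- raw[, intersect(dict$canonical, names(raw))]
  raw[raw == ""] <- NA

  df <- tibble::as_tibble(raw)
  bad_parse <- rep(FALSE, nrow(df))
  for (col in intersect(dict$numeric, names(df))) {
    num <- suppressWarnings(as.numeric(df[[col]]))
    bad_parse <- bad_parse | (!is.na(df[[col]]) & is.na(num))
    df[[col]] <- num
  }
  for (col in dict$flags) df[[col]] <- parse_flag(df[[col]])
  df$sex <- tolower(as.character(df$sex))
  df$age <- as.integer(round(df$age))

  if (any(bad_parse)) {
    if (strict) {
      stop("unparseable numeric value(s) in row id(s): ",
           paste(df$id[bad_parse], collapse = ", "))
    }
  }
  viol <- record_violations(df)
  bad <- bad_parse | viol != ""
  # NA in analysis labs alone is not a violation here (complete-case later)
  if (any(bad & !bad_parse) && strict) {
    idx <- which(bad & !bad_parse)
    stop("invalid record(s): ",
         paste(sprintf("%s (%s)", df$id[idx], viol[idx]), collapse = "; "))
  }
  n_dropped <- sum(bad)
  if (n_dropped > 0) {
    muno_log("read_cohort: dropped %d invalid record(s)", n_dropped)
    df <- df[!bad, , drop = FALSE]
  }
  if (anyDuplicated(df$id)) stop("duplicate patient id(s) in cohort")
  out <- as_cohort(df, provenance = normalizePath(path))
  attr(out, "n_dropped") <- n_dropped
  out
}

#' Write a cohort to CSV
#'
#' Writes with full double precision so that
#' `read_cohort(write_cohort(x))` is the identity on valid cohorts.
#'
#' @param cohort A cohort tibble.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  readr::write_csv(tibble::as_tibble(cohort), path, progress = FALSE)
  invisible(path)
}

#' Apply the study eligibility rules
#'
#' Retains records with dialysis vintage strictly greater than 3 months,
#' complete analysis fields, and BMI strictly below 25 kg/m2. A record
#' failing several rules is counted under the first matching reason, in the
#' fixed priority order `vintage_le_3_months`, `incomplete_fields`,
#' `bmi_ge_25`. Idempotent.
#'
#' @param cohort A cohort tibble.
#' @return The eligible subset, with the per-reason exclusion counts
#'   attached (see [exclusion_report()]).
#' @export
apply_eligibility <- function(cohort) {
  if (nrow(cohort) == 0) stop("empty cohort")
  dict <- cohort_dictionary()
  incomplete <- Reduce(`|`, lapply(dict$analysis, function(c) is.na(cohort[[c]])))
  vintage_out <- !(cohort$vintage_months > 3)
  bmi <- cohort$weight / cohort$height^2
  bmi_out <- !is.na(bmi) & bmi >= 25

  reason <- rep(NA_character_, nrow(cohort))
  reason[bmi_out] <- "bmi_ge_25"
  reason[incomplete] <- "incomplete_fields"
  reason[vintage_out] <- "vintage_le_3_months"   # highest priority last

  keep <- is.na(reason)
  reasons <- c("vintage_le_3_months", "incomplete_fields", "bmi_ge_25")
  counts <- vapply(reasons, function(r) sum(reason == r, na.rm = TRUE), 0L)
  report <- tibble::tibble(reason = reasons, n = unname(counts))
  out <- cohort[keep, , drop = FALSE]
  if (nrow(out) == 0) warning("no eligible records remain")
  muno_log("apply_eligibility: %d of %d record(s) retained (%s)",
           nrow(out), nrow(cohort),
           paste(sprintf("%s: %d", report$reason, report$n), collapse = ", "))
  out <- as_cohort(out, provenance = attr(cohort, "provenance"))
  attr(out, "exclusion_report") <- report
  attr(out, "n_input") <- nrow(cohort)
  out
}

#' Exclusion report of an eligibility-filtered cohort
#'
#' @param cohort A cohort returned by [apply_eligibility()].
#' @return A tibble with columns `reason` and `n`, or `NULL`.
#' @export
exclusion_report <- function(cohort) attr(cohort, "exclusion_report")
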