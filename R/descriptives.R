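# Group-comparison descriptives: median (IQR), Mann-Whitney U, chi-square.

#' Median and interquartile range
#'
#' Quantiles use linear interpolation between order statistics
#' (`stats::quantile` type 7); the same estimator is used for quartile
#' cutpoints in [quartile_bin()] so the two surfaces cannot drift apart.
#'
#' @param values Numeric vector (NAs dropped).
#' @return Named vector `c(q1, median, q3)`.
#' @export
median_iqr <- function(values) {
  values <- values[!is.na(values)]
  if (length(values) == 0) stop("empty input")
  q <- quantile(values, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
  c(q1 = q[1], median = q[2], q3 = q[3])
}

# exact two-sided Mann-Whitney p by enumerating group assignments;
# handles ties through midranks. Used when both groups are small.
mw_exact_p <- function(a, b) {
  nA <- length(a); nB <- length(b)
  pooled <- c(a, b)
  r <- rank(pooled)
  u_obs <- sum(r[seq_len(nA)]) - nA * (nA + 1) / 2
  mu <- nA * nB / 2
  idx <- combn(nA + nB, nA)
  u_all <- colSums(matrix(r[idx], nrow = nA)) - nA * (nA + 1) / 2
  mean(abs(u_all - mu) >= abs(u_obs - mu) - 1e-9)
}

#' Mann-Whitney U test
#'
#' U is computed from midranks (tie-corrected). The two-sided p-value is by
#' exact enumeration of group assignments when both groups have fewer than
#' 8 observations (and the enumeration is tractable), otherwise by the
#' normal approximation with continuity correction. Two identical pooled
#' samples give p = 1.
#'
#' @param group_a,group_b Numeric vectors.
#' @return List with `U` (the smaller of U and its complement), `U_a`
#'   (first-group U), `p` and `method`.
#' @export
mann_whitney <- function(group_a, group_b) {
  group_a <- group_a[!is.na(group_a)]; group_b <- group_b[!is.na(group_b)]
  nA <- length(group_a); nB <- length(group_b)
  if (nA == 0 || nB == 0) stop("both groups must be non-empty")
  r <- rank(c(group_a, group_b))
  u_a <- sum(r[seq_len(nA)]) - nA * (nA + 1) / 2
  u <- min(u_a, nA * nB - u_a)
  pooled_const <- length(unique(c(group_a, group_b))) == 1
  if (pooled_const) {
    return(list(U = u, U_a = u_a, p = 1, method = "degenerate"))
  }
  small <- nA < 8 && nB < 8 && choose(nA + nB, nA) <= 2e5
  if (small) {
    p <- mw_exact_p(group_a, group_b)
    method <- "exact"
  } else {
    p <- suppressWarnings(
      wilcox.test(group_a, group_b, exact = FALSE, correct = TRUE)$p.value)
    method <- "normal_approximation"
  }
  list(U = u, U_a = u_a, p = p, method = method)
}

#' Pearson chi-square test on a contingency table
#'
#' Without Yates continuity correction.
#'
#' @param counts Integer matrix of counts (2 x 2 or 2 x k).
#' @return List with `statistic`, `df`, `p`.
#' @export
chi_square <- function(counts) {
  counts <- as.matrix(counts)
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("counts must be non-negative integers")
  }
  if (any(rowSums(counts) == 0) || any(colSums(counts) == 0)) {
    stop("zero marginal in contingency table")
  }
  res <- suppressWarnings(chisq.test(counts, correct = FALSE))
  list(statistic = unname(res$statistic), df = unname(res$parameter),
       p = res$p.value)
}

#' Baseline-characteristics comparison table (MHNO vs MUNO)
#'
#' Continuous variables are summarised as median (IQR) per phenotype group
#' and compared by Mann-Whitney U; categorical variables as n (%) and
#' compared by chi-square. No multiplicity adjustment across rows.
#'
#' @param classified Output of [classify_cohort()].
#' @param continuous,categorical Variable names; defaults cover
#'   demographics, blood pressure, labs and the seven indices.
#' @return A tibble with one row per variable: group summaries, test name,
#'   statistic and two-sided p.
#' @export
make_table1 <- function(classified,
                        continuous = c("age", "sbp", "dbp", "wc", "bmi",
                                       "whtr", "cvai", "vai", "lap", "absi",
                                       "fpg", "tg", "hdl", "ldl", "tc"),
                        categorical = c("male", "on_antihypertensive",
                                        "on_antidiabetic", "on_lipid_lowering",
                                        "smoker_history",
                                        "education_ge_junior_high")) {
  df <- classified[classified$label %in% c("MHNO", "MUNO"), , drop = FALSE]
  df$male <- df$sex == "male"
  grp <- df$label == "MUNO"
  fmt_mi <- function(x) {
    m <- median_iqr(x)
    sprintf("%.2f (%.2f, %.2f)", m["median"], m["q1"], m["q3"])
  }
  rows <- list()
  for (v in continuous) {
    if (!v %in% names(df) || all(is.na(df[[v]]))) next
    mw <- mann_whitney(df[[v]][!grp], df[[v]][grp])
    rows[[v]] <- tibble::tibble(
      variable = v, mhno = fmt_mi(df[[v]][!grp]), muno = fmt_mi(df[[v]][grp]),
      test = "mann_whitney", statistic = mw$U, p = mw$p)
  }
  for (v in categorical) {
    if (!v %in% names(df)) next
    tab <- table(factor(df[[v]], levels = c(FALSE, TRUE)), grp)
    cs <- chi_square(tab)
    n_mhno <- sum(df[[v]][!grp]); n_muno <- sum(df[[v]][grp])
    rows[[v]] <- tibble::tibble(
      variable = v,
      mhno = sprintf("%d (%.1f%%)", n_mhno, 100 * n_mhno / sum(!grp)),
      muno = sprintf("%d (%.1f%%)", n_muno, 100 * n_muno / sum(grp)),
      test = "chi_square", statistic = cs$statistic, p = cs$p)
  }
  do.call(rbind, rows)
}
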