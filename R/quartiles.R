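# Quartile binning and covariate-adjusted logistic regression for the
# odds-ratio-by-quartile analysis.

#' Quartile binning with a fixed interval convention
#'
#' Cutpoints default to the type-7 quantiles of `values` (the same
#' estimator as [median_iqr()]). Intervals are closed on the right:
#' Q1 = (-Inf, q25], Q2 = (q25, q50], Q3 = (q50, q75], Q4 = (q75, Inf),
#' so a value exactly equal to a cutpoint falls in the lower quartile.
#'
#' @param values Numeric vector.
#' @param cutpoints Optional length-3 nondecreasing vector (q25, q50, q75);
#'   e.g. published cutpoints for external validation.
#' @return List with `cutpoints` and `quartile` (integer 1-4 per value).
#' @export
quartile_bin <- function(values, cutpoints = NULL) {
  if (is.null(cutpoints)) {
    if (length(unique(values[!is.na(values)])) < 4) {
      stop("fewer than 4 distinct values; supply cutpoints manually")
    }
    cutpoints <- quantile(values, c(0.25, 0.5, 0.75), type = 7,
                          names = FALSE, na.rm = TRUE)
    if (anyDuplicated(cutpoints)) {
      stop("tied quartile cutpoints; supply cutpoints manually")
    }
  }
  if (length(cutpoints) != 3 || is.unsorted(cutpoints)) {
    stop("cutpoints must be 3 nondecreasing values")
  }
  q <- as.integer(cut(values, c(-Inf, cutpoints, Inf), labels = FALSE,
                      right = TRUE))
  list(cutpoints = cutpoints, quartile = q)
}

#' Adjusted logistic regression of an outcome on quartile indicators
#'
#' Maximum-likelihood logistic fit (IRLS, `stats::glm`, up to 100
#' iterations) of a binary outcome on three dummy indicators for quartiles
#' 2-4 versus quartile 1, plus optional covariates. Odds ratios are
#' `exp(coef)` with 95% Wald confidence intervals `exp(coef +/- 1.96 SE)`.
#' A rank-deficient design (e.g. a constant covariate) is an error; a fit
#' that fails to converge or shows exploding standard errors (separation)
#' is returned with `flagged = TRUE` rather than as a silent number.
#'
#' @param outcome Logical (or 0/1) vector; must contain both classes.
#' @param quartile Integer vector of quartile labels 1-4
#'   (from [quartile_bin()]).
#' @param covariates Optional data frame of numeric/logical covariates.
#' @return A tibble with one row per quartile 2-4: `term`, `or`, `ci_lo`,
#'   `ci_hi`, `p`, `flagged`.
#' @export
fit_adjusted_logistic <- function(outcome, quartile, covariates = NULL) {
  y <- as.integer(outcome)
  if (length(unique(y[!is.na(y)])) < 2) stop("outcome has a single class")
  qf <- factor(quartile, levels = 1:4)
  dat <- data.frame(.y = y, .q = qf)
  if (!is.null(covariates)) {
    covariates <- as.data.frame(lapply(covariates, as.numeric))
    dat <- cbind(dat, covariates)
  }
  dat <- dat[stats::complete.cases(dat), , drop = FALSE]
  dat$.q <- droplevels(dat$.q)
  if (nlevels(dat$.q) < 2) stop("rank-deficient design: a single quartile level")
  X <- model.matrix(~ ., data = dat[, -1, drop = FALSE])
  if (qr(X)$rank < ncol(X)) {
    stop("rank-deficient design matrix (constant or collinear covariate)")
  }
  fit <- glm(.y ~ ., data = dat, family = binomial(),
             control = glm.control(epsilon = 1e-8, maxit = 100))
  cf <- coef(summary(fit))
  terms <- paste0(".q", 2:4)
  present <- terms %in% rownames(cf)
  est <- se <- p <- rep(NA_real_, 3)
  est[present] <- cf[terms[present], "Estimate"]
  se[present]  <- cf[terms[present], "Std. Error"]
  p[present]   <- cf[terms[present], "Pr(>|z|)"]
  flagged <- !fit$converged | (se > 10 & !is.na(se))
  z <- qnorm(0.975)
  tibble::tibble(
    term = paste0("Q", 2:4),
    or = exp(est), ci_lo = exp(est - z * se), ci_hi = exp(est + z * se),
    p = p, flagged = flagged | is.na(est)
  )
}

#' Odds-ratio-by-quartile table for all seven indices
#'
#' For each adiposity index: quartile-bin its values across the non-obese
#' cohort, then fit MUNO (vs MHNO) on quartile dummies adjusted for age,
#' sex, educational status and smoking history. Quartile 1 is the
#' reference (OR = 1 by construction). The fit pools the sexes with sex as
#' a covariate; the ROC analysis, by contrast, is sex-stratified.
#'
#' @param classified Output of [classify_cohort()].
#' @param indices Index columns to analyse.
#' @return List with `table2` (tibble: index, quartile, or, ci, p) and
#'   `cutpoints` (tibble: index, q25, q50, q75).
#' @export
make_table2 <- function(classified, indices = muno_indices()) {
  df <- classified[classified$label %in% c("MHNO", "MUNO"), , drop = FALSE]
  covs <- data.frame(age = df$age, sex_male = df$sex == "male",
                     education = df$education_ge_junior_high,
                     smoking = df$smoker_history)
  rows <- list(); cuts <- list()
  for (ix in indices) {
    bin <- quartile_bin(df[[ix]])
    orr <- fit_adjusted_logistic(df$label == "MUNO", bin$quartile, covs)
    rows[[ix]] <- cbind(tibble::tibble(index = ix), orr)
    cuts[[ix]] <- tibble::tibble(index = ix, q25 = bin$cutpoints[1],
                                 q50 = bin$cutpoints[2], q75 = bin$cutpoints[3])
  }
  list(table2 = do.call(rbind, rows), cutpoints = do.call(rbind, cuts))
}
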