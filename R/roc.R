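# Empirical ROC curves, Youden-optimal cutoffs, and the DeLong test for
# paired (same-subject) AUC comparison. The classification direction is
# fixed for all indices: higher score predicts MUNO.

check_labels <- function(labels) {
  labels <- as.logical(labels)
  if (any(is.na(labels))) stop("labels must be 0/1 or logical, no NA")
  if (all(labels) || !any(labels)) stop("both classes must be present")
  labels
}

#' Empirical ROC curve points
#'
#' One vertex per distinct score (ties grouped), thresholds descending,
#' classification rule "positive if score >= threshold". The curve starts
#' at (0, 0) and ends at (1, 1) and is monotone nondecreasing in both
#' coordinates.
#'
#' @param scores Numeric vector; higher = more disease-like.
#' @param labels Binary vector, `TRUE`/1 = positive class.
#' @return A tibble with `threshold`, `fpr`, `tpr`.
#' @export
roc_points <- function(scores, labels) {
  labels <- check_labels(labels)
  if (length(scores) != length(labels)) stop("length mismatch")
  if (any(is.na(scores))) stop("NA scores not allowed")
  n1 <- sum(labels); n0 <- sum(!labels)
  th <- sort(unique(scores), decreasing = TRUE)
  pos_at <- vapply(split(labels, scores), sum, 0)            # by ascending score
  tot_at <- vapply(split(labels, scores), length, 0L)
  # reorder to descending threshold
  pos_at <- rev(pos_at); tot_at <- rev(tot_at)
  tp <- cumsum(pos_at); fp <- cumsum(tot_at - pos_at)
  tibble::tibble(
    threshold = c(Inf, th),
    fpr = unname(c(0, fp / n0)),
    tpr = unname(c(0, tp / n1))
  )
}

#' Area under an ROC curve by trapezoid integration
#'
#' Equals the Mann-Whitney pair statistic
#' (#concordant + 1/2 #tied) / (n1 * n0) exactly.
#'
#' @param points Output of [roc_points()].
#' @return AUC in \[0, 1\].
#' @export
auc_trapezoid <- function(points) {
  fpr <- points$fpr; tpr <- points$tpr
  sum(diff(fpr) * (tpr[-1] + tpr[-length(tpr)]) / 2)
}

# placement values (DeLong structural components), midrank-based.
# V10: per positive subject; V01: per negative subject. mean(V10) = AUC.
delong_placements <- function(scores, labels) {
  x <- scores[labels]; y <- scores[!labels]
  n1 <- length(x); n0 <- length(y)
  r_all <- rank(c(x, y))
  v10 <- (r_all[seq_len(n1)] - rank(x)) / n0
  v01 <- 1 - (r_all[n1 + seq_len(n0)] - rank(y)) / n1
  list(v10 = v10, v01 = v01, auc = mean(v10), n1 = n1, n0 = n0)
}

#' AUC with DeLong variance and normal-theory confidence interval
#'
#' @param scores,labels As in [roc_points()].
#' @param level Confidence level (default 0.95).
#' @return List with `auc`, `se`, `ci_lo`, `ci_hi` (clamped to \[0, 1\])
#'   and `p_vs_half` (two-sided test of AUC = 0.5).
#' @export
auc_delong_ci <- function(scores, labels, level = 0.95) {
  labels <- check_labels(labels)
  pl <- delong_placements(scores, labels)
  v <- var(pl$v10) / pl$n1 + var(pl$v01) / pl$n0
  se <- sqrt(max(v, 0))
  z <- qnorm(1 - (1 - level) / 2)
  p <- if (se > 0) 2 * pnorm(-abs((pl$auc - 0.5) / se)) else
    as.numeric(pl$auc == 0.5)
  list(auc = pl$auc, se = se,
       ci_lo = max(0, pl$auc - z * se), ci_hi = min(1, pl$auc + z * se),
       p_vs_half = p)
}

#' Youden-optimal cutoff
#'
#' Scans the observed distinct score values as candidate cutoffs (rule:
#' positive if score >= cutoff) and maximises the Youden index
#' J = sensitivity + specificity - 1. A tie in J is broken by the smallest
#' cutoff.
#'
#' @param scores,labels As in [roc_points()].
#' @return List with `cutoff`, `sensitivity`, `specificity`, `youden`.
#' @export
youden_cutoff <- function(scores, labels) {
  labels <- check_labels(labels)
  cand <- sort(unique(scores))            # ascending: ties -> smallest cutoff
  n1 <- sum(labels); n0 <- sum(!labels)
  # counts at each distinct value (ascending)
  pos_at <- vapply(split(labels, scores), sum, 0)
  tot_at <- vapply(split(labels, scores), length, 0L)
  # sens(c) = P(score >= c | pos): reverse cumulative sums
  sens <- rev(cumsum(rev(pos_at))) / n1
  spec <- (cumsum(tot_at - pos_at) - (tot_at - pos_at)) / n0  # P(score < c | neg)
  j <- sens + spec - 1
  # ties in J (within FP noise) resolve to the smallest cutoff
  best <- which(j >= max(j) - 1e-12)[1]
  list(cutoff = cand[best], sensitivity = unname(sens[best]),
       specificity = unname(spec[best]), youden = unname(j[best]))
}

#' DeLong test for two correlated AUCs
#'
#' Both indices are scored on the same subjects with the same labels.
#' Placement values per class give a 2x2 covariance matrix per class;
#' `Var(AUC_A - AUC_B) = (S10_AA + S10_BB - 2 S10_AB)/n1 + (S01_.)/n0`;
#' `Z = (AUC_A - AUC_B) / sqrt(Var)` with a two-sided standard-normal
#' p-value. Zero variance (e.g. identical score vectors) returns Z = 0,
#' p = 1 with `degenerate = TRUE`.
#'
#' @param scores_a,scores_b Paired score vectors.
#' @param labels Shared binary labels.
#' @return List with `auc_a`, `auc_b`, `delta`, `var_delta`, `z`, `p`,
#'   `degenerate`.
#' @export
delong_test <- function(scores_a, scores_b, labels) {
  labels <- check_labels(labels)
  if (length(scores_a) != length(labels) ||
      length(scores_b) != length(labels)) stop("length mismatch")
  pa <- delong_placements(scores_a, labels)
  pb <- delong_placements(scores_b, labels)
  s10 <- cov(cbind(pa$v10, pb$v10))
  s01 <- cov(cbind(pa$v01, pb$v01))
  v <- (s10[1, 1] + s10[2, 2] - 2 * s10[1, 2]) / pa$n1 +
       (s01[1, 1] + s01[2, 2] - 2 * s01[1, 2]) / pa$n0
  delta <- pa$auc - pb$auc
  if (!is.finite(v) || v <= .Machine$double.eps) {
    # degenerate variance: identical AUCs give the null result; a real AUC
    # difference with no sampling variability is off the normal scale
    if (abs(delta) <= sqrt(.Machine$double.eps)) {
      return(list(auc_a = pa$auc, auc_b = pb$auc, delta = delta,
                  var_delta = max(v, 0), z = 0, p = 1, degenerate = TRUE))
    }
    return(list(auc_a = pa$auc, auc_b = pb$auc, delta = delta,
                var_delta = max(v, 0), z = sign(delta) * Inf, p = 0,
                degenerate = TRUE))
  }
  z <- delta / sqrt(v)
  list(auc_a = pa$auc, auc_b = pb$auc, delta = delta, var_delta = v,
       z = z, p = 2 * pnorm(-abs(z)), degenerate = FALSE)
}

default_delong_pairs <- function() {
  list(c("bmi", "wc"), c("bmi", "whtr"), c("bmi", "absi"),
       c("wc", "whtr"), c("wc", "absi"), c("wc", "cvai"),
       c("whtr", "cvai"), c("whtr", "absi"), c("lap", "vai"))
}

#' Sex-stratified ROC and DeLong comparison tables
#'
#' Per sex stratum and index: AUC with 95% DeLong CI, the test of
#' AUC = 0.5, and the Youden-optimal cutoff with its sensitivity and
#' specificity. Per stratum and configured index pair: the paired DeLong
#' comparison (Z reported as AUC of the first index minus the second).
#' A stratum with a single phenotype class is skipped with a log entry.
#'
#' @param classified Output of [classify_cohort()]; rows with label
#'   `not_applicable` are ignored.
#' @param indices Index columns to analyse.
#' @param pairs List of 2-vectors of index names to compare.
#' @return List with `table3` (per index x sex), `table4` (per pair x sex)
#'   and `roc_curves` (curve coordinates for plotting).
#' @export
run_roc_table <- function(classified, indices = muno_indices(),
                          pairs = default_delong_pairs()) {
  df <- classified[classified$label %in% c("MHNO", "MUNO"), , drop = FALSE]
  t3 <- list(); t4 <- list(); curves <- list()
  for (sx in c("male", "female")) {
    sub <- df[df$sex == sx, , drop = FALSE]
    y <- sub$label == "MUNO"
    if (length(unique(y)) < 2) {
      muno_log("run_roc_table: stratum %s has a single class; skipped", sx)
      next
    }
    for (ix in indices) {
      ci <- auc_delong_ci(sub[[ix]], y)
      yd <- youden_cutoff(sub[[ix]], y)
      t3[[paste(sx, ix)]] <- tibble::tibble(
        sex = sx, index = ix, auc = ci$auc, ci_lo = ci$ci_lo,
        ci_hi = ci$ci_hi, p = ci$p_vs_half, cutoff = yd$cutoff,
        sensitivity = yd$sensitivity, specificity = yd$specificity,
        youden = yd$youden)
      pts <- roc_points(sub[[ix]], y)
      curves[[paste(sx, ix)]] <- cbind(tibble::tibble(sex = sx, index = ix), pts)
    }
    for (pr in pairs) {
      dl <- delong_test(sub[[pr[1]]], sub[[pr[2]]], y)
      t4[[paste(sx, pr[1], pr[2])]] <- tibble::tibble(
        sex = sx, index_a = pr[1], index_b = pr[2],
        auc_a = dl$auc_a, auc_b = dl$auc_b, z = dl$z, p = dl$p,
        degenerate = dl$degenerate)
    }
  }
  list(table3 = do.call(rbind, t3), table4 = do.call(rbind, t4),
       roc_curves = do.call(rbind, curves))
}
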