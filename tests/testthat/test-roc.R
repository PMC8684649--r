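test_that("ROC curve endpoints, monotonicity and the canonical cases hold", {
  pts <- roc_points(c(1, 2, 3, 4), c(0, 0, 1, 1))
  expect_equal(pts$fpr[1], 0); expect_equal(pts$tpr[1], 0)
  expect_equal(pts$fpr[nrow(pts)], 1); expect_equal(pts$tpr[nrow(pts)], 1)
  expect_equal(auc_trapezoid(pts), 1)
  # all scores tied: the diagonal
  tied <- roc_points(rep(2, 6), c(1, 0, 1, 0, 1, 0))
  expect_equal(auc_trapezoid(tied), 0.5)
  expect_true(all(diff(tied$fpr) >= 0) && all(diff(tied$tpr) >= 0))
  # 5-point mixed case against exhaustive pair counting
  s <- c(3, 1, 2, 4, 2); l <- c(1, 0, 0, 1, 1)
  expect_equal(auc_trapezoid(roc_points(s, l)), auc_pair_oracle(s, l))
  expect_error(roc_points(1:4, c(1, 1, 1, 1)), "both classes")
})

test_that("trapezoid AUC equals pair counting exactly on random small inputs", {
  set.seed(407)
  for (i in 1:100) {
    inst <- random_roc_instance()
    expect_equal(auc_trapezoid(roc_points(inst$scores, inst$labels)),
                 auc_pair_oracle(inst$scores, inst$labels),
                 tolerance = 1e-13)
  }
})

test_that("negating scores maps AUC to its complement", {
  set.seed(408)
  for (i in 1:20) {
    inst <- random_roc_instance()
    a1 <- auc_trapezoid(roc_points(inst$scores, inst$labels))
    a2 <- auc_trapezoid(roc_points(-inst$scores, inst$labels))
    expect_equal(a1 + a2, 1, tolerance = 1e-12)
  }
})

test_that("the Youden scan equals brute-force maximisation", {
  # perfect separation
  yd <- youden_cutoff(c(1, 2, 8, 9), c(0, 0, 1, 1))
  expect_equal(yd$cutoff, 8)
  expect_equal(yd$sensitivity, 1); expect_equal(yd$specificity, 1)
  expect_equal(yd$youden, 1)
  # 6-point mixed fixture
  s <- c(0.2, 0.5, 0.5, 0.9, 1.4, 2.0); l <- c(0, 0, 1, 0, 1, 1)
  orc <- youden_oracle(s, l)
  got <- youden_cutoff(s, l)
  expect_equal(got$cutoff, orc$cutoff)
  expect_equal(got$youden, orc$j)
  set.seed(409)
  for (i in 1:60) {
    inst <- random_roc_instance()
    got <- youden_cutoff(inst$scores, inst$labels)
    orc <- youden_oracle(inst$scores, inst$labels)
    expect_equal(got$youden, orc$j, tolerance = 1e-12)
    expect_equal(got$cutoff, orc$cutoff)   # smallest cutoff on ties
    expect_equal(got$youden, got$sensitivity + got$specificity - 1)
  }
})

test_that("DeLong self-comparison is exactly null and the test is antisymmetric", {
  set.seed(410)
  s <- rnorm(40); l <- rep(c(0, 1), 20)
  self <- delong_test(s, s, l)
  expect_identical(self$z, 0); expect_identical(self$p, 1)
  expect_true(self$degenerate)
  s2 <- rnorm(40) + l
  ab <- delong_test(s, s2, l); ba <- delong_test(s2, s, l)
  expect_equal(ab$z, -ba$z); expect_equal(ab$p, ba$p)
})

test_that("maximal contrast between a perfect and an inverted index is detected", {
  scores <- c(1, 2, 3, 10, 11, 12); labels <- c(0, 0, 0, 1, 1, 1)
  res <- delong_test(scores, -scores, labels)
  expect_equal(res$delta, 1)
  expect_lt(res$p, 0.05)
})

test_that("AUC and DeLong results agree with an independent implementation", {
  skip_if_not_installed("pROC")
  set.seed(411)
  n <- 120
  l <- rbinom(n, 1, 0.5)
  a <- rnorm(n) + 0.8 * l; b <- rnorm(n) + 0.5 * l
  ci <- auc_delong_ci(a, l)
  ref <- pROC::roc(l, a, quiet = TRUE, direction = "<")
  expect_equal(ci$auc, as.numeric(pROC::auc(ref)), tolerance = 1e-12)
  ref_ci <- as.numeric(pROC::ci.auc(ref, method = "delong"))
  expect_equal(c(ci$ci_lo, ci$ci_hi), ref_ci[c(1, 3)], tolerance = 1e-9)
  ours <- delong_test(a, b, l)
  ref_b <- pROC::roc(l, b, quiet = TRUE, direction = "<")
  theirs <- pROC::roc.test(ref, ref_b, method = "delong", paired = TRUE)
  expect_equal(ours$p, theirs$p.value, tolerance = 1e-9)
  expect_equal(abs(ours$z), abs(as.numeric(theirs$statistic)), tolerance = 1e-9)
})

test_that("the stratified ROC table composes the per-operation results", {
  cl <- classify_cohort(apply_eligibility(
    generate_cohort(cohort_config(n = 400, seed = 19))))
  res <- run_roc_table(cl)
  expect_equal(nrow(res$table3), 14)   # 7 indices x 2 sexes
  expect_equal(nrow(res$table4), 18)   # 9 pairs x 2 sexes
  male <- cl[cl$sex == "male", ]
  y <- male$label == "MUNO"
  direct <- auc_delong_ci(male$vai, y)
  row <- res$table3[res$table3$sex == "male" & res$table3$index == "vai", ]
  expect_equal(row$auc, direct$auc)
  expect_equal(row$ci_lo, direct$ci_lo)
  yd <- youden_cutoff(male$vai, y)
  expect_equal(row$cutoff, yd$cutoff)
  expect_true(all(res$table3$ci_lo <= res$table3$auc &
                    res$table3$auc <= res$table3$ci_hi))
  expect_equal(res$table3$youden,
               res$table3$sensitivity + res$table3$specificity - 1)
  # identical index columns give p = 1
  cl$fake <- cl$vai
  same <- run_roc_table(cl, indices = c("vai", "fake"),
                        pairs = list(c("vai", "fake")))
  expect_true(all(same$table4$p == 1))
})
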