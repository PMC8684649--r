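# Fixtures built in code, plus brute-force oracles kept independent of the
# implementation paths they check.

options(munodx.verbose = FALSE)

make_record <- function(id = "P01", age = 50L, sex = "male", height = 1.70,
                        weight = 65, wc = 80, sbp = 120, dbp = 75,
                        fpg = 5.0, tg = 1.2, hdl = 1.4, ldl = 2.2, tc = 3.9,
                        on_antihypertensive = FALSE, on_antidiabetic = FALSE,
                        on_lipid_lowering = FALSE, smoker_history = FALSE,
                        education_ge_junior_high = TRUE,
                        vintage_months = 24) {
  tibble::tibble(id = id, age = age, sex = sex, height = height,
                 weight = weight, wc = wc, sbp = sbp, dbp = dbp, fpg = fpg,
                 tg = tg, hdl = hdl, ldl = ldl, tc = tc,
                 on_antihypertensive = on_antihypertensive,
                 on_antidiabetic = on_antidiabetic,
                 on_lipid_lowering = on_lipid_lowering,
                 smoker_history = smoker_history,
                 education_ge_junior_high = education_ge_junior_high,
                 vintage_months = vintage_months)
}

make_cohort <- function(...) {
  rows <- list(...)
  do.call(rbind, lapply(seq_along(rows), function(i) {
    r <- rows[[i]]
    r$id <- sprintf("P%02d", i)
    r
  }))
}

# AUC by exhaustive positive-negative pair counting (ties count half)
auc_pair_oracle <- function(scores, labels) {
  x <- scores[as.logical(labels)]; y <- scores[!as.logical(labels)]
  total <- 0
  for (xi in x) for (yj in y) {
    total <- total + (xi > yj) + 0.5 * (xi == yj)
  }
  total / (length(x) * length(y))
}

# Youden-optimal cutoff by brute force over all observed thresholds
youden_oracle <- function(scores, labels) {
  labels <- as.logical(labels)
  best <- list(j = -Inf, cutoff = NA)
  for (cand in sort(unique(scores))) {
    sens <- mean(scores[labels] >= cand)
    spec <- mean(scores[!labels] < cand)
    j <- sens + spec - 1
    if (j > best$j + 1e-12) best <- list(j = j, cutoff = cand,
                                         sens = sens, spec = spec)
  }
  best
}

random_roc_instance <- function(max_n = 12) {
  repeat {
    n <- sample(4:max_n, 1)
    labels <- runif(n) < 0.5
    if (any(labels) && !all(labels)) break
  }
  scores <- sample(1:6, n, replace = TRUE) + ifelse(runif(n) < 0.5, 0, 0.5)
  list(scores = scores, labels = labels)
}
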