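test_that("BMI and WHtR match hand-substituted values", {
  expect_equal(compute_bmi(1, 1), 1)
  expect_equal(compute_bmi(80, 2), 20)
  expect_equal(compute_bmi(70, 1.75), 22.8571428571, tolerance = 1e-10)
  expect_equal(compute_whtr(100, 2), 0.5)
  expect_equal(compute_whtr(48, 1), 0.48)
  expect_equal(compute_whtr(81.5, 1.70), 0.479411764706, tolerance = 1e-10)
  expect_error(compute_bmi(-1, 1.7), "weight")
  expect_error(compute_whtr(80, 0), "height")
})

test_that("LAP uses the sex anchors and is not truncated at zero", {
  expect_equal(compute_lap("male", 65, 1.9), 0)
  expect_equal(compute_lap("female", 58, 0.7), 0)
  expect_equal(compute_lap("male", 90, 2.0), 50)
  expect_lt(compute_lap("female", 55, 1.2), 0)   # below anchor: kept negative
  expect_error(compute_lap("unknown", 80, 1.2), "sex")
})

test_that("VAI equals 1 in the unity configuration and matches hand substitution", {
  bmi <- 22
  expect_equal(compute_vai("male", 39.68 + 1.88 * bmi, bmi, 1.03, 1.31), 1)
  expect_equal(compute_vai("female", 36.58 + 1.89 * bmi, bmi, 0.81, 1.52), 1)
  expect_equal(compute_vai("male", 85, 22, 2.0, 1.0), 2.66798608382,
               tolerance = 1e-10)
})

test_that("CVAI matches the printed linear coefficients for both sexes", {
  # TG = 1 zeroes the log term
  expect_equal(compute_cvai("male", 54, 21, 80, 1.0, 1.2),
               -267.93 + 0.68 * 54 + 0.03 * 21 + 4 * 80 - 16.32 * 1.2)
  expect_equal(compute_cvai("male", 54, 21, 80, 1.5, 1.2), 73.7100076992,
               tolerance = 1e-10)
  expect_equal(compute_cvai("female", 54, 21, 80, 1.5, 1.2), 76.4593884601,
               tolerance = 1e-10)
  expect_error(compute_cvai("male", 54, 21, 80, 0, 1.2), "tg")
})

test_that("ABSI converts WC to metres and matches exact power cases", {
  expect_equal(compute_absi(100, 1, 1), 1)
  expect_equal(compute_absi(80, 8, 1), 0.80 / 4)   # 8^(2/3) = 4
  expect_equal(compute_absi(81.5, 22, 1.70), 0.0796131291886,
               tolerance = 1e-10)
})

test_that("indices are monotone in their risk direction on random grids", {
  set.seed(401)
  for (i in 1:50) {
    sex <- sample(c("male", "female"), 1)
    wc <- runif(1, 70, 110); bmi <- runif(1, 17, 30)  # WC above both anchors
    tg <- runif(1, 0.5, 4); hdl <- runif(1, 0.6, 2.5)
    age <- runif(1, 20, 85); h <- runif(1, 1.4, 1.95)
    up <- 1.1
    expect_gt(compute_vai(sex, wc, bmi, tg * up, hdl),
              compute_vai(sex, wc, bmi, tg, hdl))
    expect_lt(compute_vai(sex, wc, bmi, tg, hdl * up),
              compute_vai(sex, wc, bmi, tg, hdl))
    expect_gt(compute_lap(sex, wc, tg * up), compute_lap(sex, wc, tg))
    expect_gt(compute_cvai(sex, age, bmi, wc, tg * up, hdl),
              compute_cvai(sex, age, bmi, wc, tg, hdl))
    expect_lt(compute_cvai(sex, age, bmi, wc, tg, hdl * up),
              compute_cvai(sex, age, bmi, wc, tg, hdl))
    for (f in list(function(w) compute_lap(sex, w, tg),
                   function(w) compute_cvai(sex, age, bmi, w, tg, hdl),
                   function(w) compute_absi(w, bmi, h),
                   function(w) compute_whtr(w, h))) {
      expect_gt(f(wc * up), f(wc))
    }
  }
})

test_that("male and female formulas differ on generic inputs", {
  set.seed(402)
  for (i in 1:25) {
    wc <- runif(1, 60, 110); bmi <- runif(1, 17, 30)
    tg <- runif(1, 0.5, 4); hdl <- runif(1, 0.6, 2.5); age <- runif(1, 20, 85)
    expect_false(compute_vai("male", wc, bmi, tg, hdl) ==
                   compute_vai("female", wc, bmi, tg, hdl))
    expect_false(compute_lap("male", wc, tg) == compute_lap("female", wc, tg))
    expect_false(compute_cvai("male", age, bmi, wc, tg, hdl) ==
                   compute_cvai("female", age, bmi, wc, tg, hdl))
  }
})

test_that("compute_panel equals the composition of the scalar operations", {
  cohort <- generate_cohort(cohort_config(n = 40, seed = 5))
  panel <- compute_panel(cohort)
  bmi <- compute_bmi(cohort$weight, cohort$height)
  expect_equal(panel$bmi, bmi)
  expect_equal(panel$wc, cohort$wc)
  expect_equal(panel$whtr, compute_whtr(cohort$wc, cohort$height))
  expect_equal(panel$whtr, panel$wc / (100 * cohort$height))
  expect_equal(panel$vai,
               compute_vai(cohort$sex, cohort$wc, bmi, cohort$tg, cohort$hdl))
  expect_equal(panel$cvai,
               compute_cvai(cohort$sex, cohort$age, bmi, cohort$wc,
                            cohort$tg, cohort$hdl))
  expect_equal(panel$absi, compute_absi(cohort$wc, bmi, cohort$height))
  expect_equal(panel$lap, compute_lap(cohort$sex, cohort$wc, cohort$tg))
})

test_that("the unity-VAI configuration survives the panel path", {
  rec <- make_record(sex = "male", height = 1.70, weight = 22 * 1.7^2,
                     wc = 39.68 + 1.88 * 22, tg = 1.03, hdl = 1.31)
  panel <- compute_panel(rec)
  expect_equal(panel$vai, 1, tolerance = 1e-12)
})
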