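# generator: covariates, treatment, outcome, missingness

test_that("covariate generator matches the stated moments", {
  x <- generate_covariates(scenario_spec(2e5, seed = 1))
  n <- nrow(x)
  # sd(X2) -> 1, cor -> 0.5, residual sd -> sqrt(0.75); 3 MC SEs each
  expect_lt(abs(sd(x[, "X2"]) - 1), 3 / sqrt(2 * n))
  expect_lt(abs(cor(x[, "X1"], x[, "X2"]) - 0.5),
            3 * (1 - 0.25) / sqrt(n))
  eps_hat <- x[, "X2"] - 0.5 * x[, "X1"]
  expect_lt(abs(sd(eps_hat) - sqrt(0.75)), 3 * sqrt(0.75) / sqrt(2 * n))
})

test_that("generation is seed-deterministic and validates inputs", {
  a <- generate_covariates(scenario_spec(2, seed = 42))
  b <- generate_covariates(scenario_spec(2, seed = 42))
  expect_identical(a, b)
  expect_error(scenario_spec(1), "n_subjects")
  expect_error(scenario_spec(10, outcome_noise_sd = 0), "outcome_noise_sd")
  d1 <- simulate_scenario(scenario_spec(50, 1, seed = 9))
  d2 <- simulate_scenario(scenario_spec(50, 1, seed = 9))
  expect_identical(d1$covariates, d2$covariates)
  expect_identical(d1$outcome, d2$outcome)
})

test_that("treatment model produces the stated assignment probabilities", {
  x <- generate_covariates(scenario_spec(1e5, seed = 2))
  tr <- generate_treatment(x, seed = 3)
  # frozen MC value of E[expit(-0.8 + 0.5 X1 + 0.5 X2)] = 0.3339
  expect_lt(abs(mean(tr) - 0.3339), 3 * sqrt(0.334 * 0.666 / 1e5) + 0.005)
  # two independent seeds agree within binomial error
  tr2 <- generate_treatment(x, seed = 4)
  expect_lt(abs(mean(tr) - mean(tr2)), 3 * sqrt(2 * 0.3 * 0.7 / 1e5))
  xm <- x; xm[1, 1] <- NA
  expect_error(generate_treatment(xm), "complete")
})

test_that("outcome regression recovers the generating coefficients", {
  # OLS on the full design is the independent oracle
  for (eff in c(0, 1)) {
    spec <- scenario_spec(1e5, eff, seed = 5)
    d <- simulate_scenario(spec)
    fit <- lm(d$outcome ~ d$treatment + d$covariates[, "X1"] +
                d$covariates[, "X2"])
    se <- summary(fit)$coefficients[, 2]
    expect_lt(abs(coef(fit)[2] - eff), 3 * se[2])
    expect_lt(abs(coef(fit)[3] - 1), 3 * se[3])
    expect_lt(abs(coef(fit)[4] - 1), 3 * se[4])
  }
})

test_that("offset calibration solves the rate equation", {
  # all-zero drivers at rate 0.5 -> exactly 0
  expect_equal(calibrate_offset("MAR", 0.5, rep(0, 10)), 0, tolerance = 1e-9)
  # frozen bisection-oracle value for drivers {-1,0,1}, rate 0.3
  C <- calibrate_offset("MNAR", 0.3, c(-1, 0, 1))
  expect_equal(C, -0.978578, tolerance = 1e-4)
  expect_equal(C, bisect_offset(c(-1, 0, 1), 0.3), tolerance = 1e-6)
  expect_lt(abs(mean(plogis(c(-1, 0, 1) + C)) - 0.3), 1e-6)
  # large centered normal sample -> C near 0 at rate 0.5
  set.seed(8)
  expect_lt(abs(calibrate_offset("MAR", 0.5, rnorm(2e5))), 0.02)
  expect_error(calibrate_offset("MAR", 1.2, 0), "target_rate")
  expect_error(calibrate_offset("MCAR", 0.5, 0), "MAR/MNAR")
})

test_that("imposed missingness hits its target rates", {
  d <- simulate_scenario(scenario_spec(1e4, 0, seed = 13))
  # MCAR masks an exact count
  for (rate in c(0.2, 0.5, 0.8)) {
    mk <- impose_missingness(d, missingness_spec("MCAR", rate), seed = 1)
    expect_equal(sum(mk$mask[, "X2"]), round(1e4 * rate))
    expect_equal(sum(mk$mask[, "X1"]), 0)
  }
  # MAR / MNAR are Bernoulli with calibrated C: within 3 binomial SEs
  for (mech in c("MAR", "MNAR")) {
    for (rate in c(0.2, 0.5, 0.8)) {
      mk <- impose_missingness(d, missingness_spec(mech, rate), seed = 2)
      expect_lt(abs(mean(mk$mask[, "X2"]) - rate),
                3 * sqrt(rate * (1 - rate) / 1e4))
    }
  }
  # rate 0 is the identity
  mk0 <- impose_missingness(d, missingness_spec("MCAR", 0), seed = 3)
  expect_identical(mk0$covariates, d$covariates)
  expect_true(all(mk0$mask == 0))
})

test_that("mechanisms leave the right dependence signature", {
  d <- simulate_scenario(scenario_spec(1e5, 0, seed = 17))
  mnar <- impose_missingness(d, missingness_spec("MNAR", 0.5), seed = 1)
  m <- mnar$mask[, "X2"] == 1
  # higher X2 -> more masking: masked true values exceed unmasked on average
  expect_gt(mean(mnar$truth[m, "X2"]), mean(mnar$truth[!m, "X2"]) + 0.3)
  mcar <- impose_missingness(d, missingness_spec("MCAR", 0.5), seed = 1)
  mc <- mcar$mask[, "X2"]
  # MCAR masking independent of both columns
  expect_lt(abs(cor(mc, mcar$truth[, "X1"])), 3 / sqrt(1e5))
  expect_lt(abs(cor(mc, mcar$truth[, "X2"])), 3 / sqrt(1e5))
  # same seed -> bit-identical masked dataset
  again <- impose_missingness(d, missingness_spec("MNAR", 0.5), seed = 1)
  expect_identical(again$covariates, mnar$covariates)
})

test_that("extreme rates warn instead of failing", {
  d <- simulate_scenario(scenario_spec(40, 0, seed = 19))
  w <- capture_warnings(impose_missingness(d, missingness_spec("MCAR", 0.99),
                                           seed = 1))
  expect_true(any(grepl("fully missing", w)))
})

test_that("real-world masking follows the stated scheme", {
  tab <- synthetic_lalonde(seed = 21)
  # MCAR: exactly round(0.2 * 614) = 123 cells in each target column
  mk <- impose_realworld_missingness(
    tab, missingness_spec("MCAR", 0.2, target_columns = c("re74", "re75")),
    seed = 1)
  expect_equal(colSums(attr(mk, "mask")), c(re74 = 123, re75 = 123))
  expect_true(all(is.na(mk$re74[attr(mk, "mask")[, "re74"] == 1])))
  # rate 0 -> identity
  mk0 <- impose_realworld_missingness(
    tab, missingness_spec("MAR", 0, target_columns = c("re74", "re75")),
    seed = 1)
  expect_identical(mk0$re74, tab$re74)
  # MAR rate 0.5 within binomial error (calibration contract)
  mk5 <- impose_realworld_missingness(
    tab, missingness_spec("MAR", 0.5, target_columns = c("re74", "re75")),
    seed = 2)
  expect_lt(abs(mean(attr(mk5, "mask")) - 0.5), 3 * sqrt(0.25 / 614))
  # missing drivers rejected
  bad <- tab; bad$age[1] <- NA
  expect_error(impose_realworld_missingness(
    bad, missingness_spec("MCAR", 0.2, target_columns = "re74")),
    "observed")
})

test_that("CSV round trip with JSON sidecar preserves the dataset", {
  d <- impose_missingness(simulate_scenario(scenario_spec(60, 1, seed = 23)),
                          missingness_spec("MCAR", 0.3), seed = 5)
  path <- tempfile(fileext = ".csv")
  write_dataset_csv(d, path, meta = list(note = "round-trip"))
  back <- read_dataset_csv(path)
  expect_equal(back$covariates[, "X1"], d$covariates[, "X1"],
               tolerance = 1e-12, ignore_attr = TRUE)
  expect_identical(is.na(back$covariates[, "X2"]),
                   unname(is.na(d$covariates[, "X2"])))
  expect_equal(back$treatment, d$treatment)
  expect_equal(back$outcome, d$outcome, tolerance = 1e-12)
  unlink(c(path, paste0(path, ".json")))
})
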