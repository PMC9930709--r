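# multi-task network: encoding, loss, training, prediction, imputation

test_that("input encoding standardizes, zero-fills and appends the mask", {
  d <- make_tiny_masked()
  enc <- encode_inputs(d)
  expect_equal(dim(enc), c(6, 4))
  # masked cells: 0 in the value block, 1 in the mask block
  expect_equal(unname(enc[2, "X2"]), 0)
  expect_equal(unname(enc[2, "miss_X2"]), 1)
  expect_equal(sum(enc[, "miss_X1"]), 0)
  # observed entries standardized with observed-only center/scale
  obs <- d$covariates[d$mask[, "X2"] == 0, "X2"]
  expect_equal(unname(enc[1, "X2"]), (0.2 - mean(obs)) / sd(obs),
               tolerance = 1e-12)
  # explicit center/scale: value 5 in a column with mean 3, sd 2 -> 1.0
  std <- list(center = c(3, 0), scale = c(2, 1),
              is_binary = c(FALSE, FALSE), columns = c("X1", "X2"))
  d2 <- observed_dataset(covariate_matrix(cbind(X1 = c(5, 3), X2 = c(0, 1))),
                         c(1, 0), c(0, 0))
  expect_equal(unname(encode_inputs(d2, std)[1, "X1"]), 1.0)
  # an entirely missing column is rejected
  x <- covariate_matrix(cbind(X1 = c(1, 2, 1, 0), X2 = rep(NA_real_, 4)))
  dd <- observed_dataset(x, c(0, 1, 0, 1), rnorm(4))
  expect_error(encode_inputs(dd), "entirely missing")
})

test_that("joint loss matches hand arithmetic", {
  d <- make_tiny_masked()
  std <- fit_standardization_for_test(d)
  xstd <- (ifelse(is.na(d$covariates), 0, d$covariates) -
             matrix(std$center, 6, 2, byrow = TRUE)) /
    matrix(std$scale, 6, 2, byrow = TRUE)
  # perfect outputs -> zero loss
  perfect <- list(reconstruction = xstd, propensity = d$treatment,
                  missing_pattern = d$mask)
  expect_equal(mtnn_joint_loss(perfect, d)$total, 0)
  # uninformative propensity with balanced treatment, weights (0,1,0) -> ln 2
  unif <- list(reconstruction = xstd, propensity = rep(0.5, 6),
               missing_pattern = d$mask)
  expect_equal(mtnn_joint_loss(unif, d, weights = c(0, 1, 0))$total, log(2),
               tolerance = 1e-12)
  # random small instance vs scalar arithmetic
  set.seed(31)
  out <- list(reconstruction = matrix(rnorm(12), 6, 2),
              propensity = runif(6, 0.1, 0.9),
              missing_pattern = matrix(runif(12, 0.1, 0.9), 6, 2))
  got <- mtnn_joint_loss(out, d, weights = c(2, 1, 0.5))
  obs <- 1 - d$mask
  l_rec <- sum(obs * (out$reconstruction - xstd)^2) / sum(obs)
  l_p <- -mean(d$treatment * log(out$propensity) +
                 (1 - d$treatment) * log(1 - out$propensity))
  l_m <- -mean(d$mask * log(out$missing_pattern) +
                 (1 - d$mask) * log(1 - out$missing_pattern))
  expect_equal(got$total, 2 * l_rec + 1 * l_p + 0.5 * l_m, tolerance = 1e-12)
  expect_equal(unname(got$per_task), c(l_rec, l_p, l_m), tolerance = 1e-12)
  # non-finite outputs abort
  bad <- out; bad$propensity[1] <- NaN
  expect_error(mtnn_joint_loss(bad, d), "non-finite")
})

test_that("training minimizes the loss deterministically", {
  d <- impose_missingness(make_sim_data(300, 0, seed = 33),
                          missingness_spec("MCAR", 0.3), seed = 1)
  cfg <- mtnn_config(max_epochs = 60, seed = 7)
  m1 <- suppressWarnings(mtnn_train(d, cfg))
  m2 <- suppressWarnings(mtnn_train(d, cfg))
  expect_identical(m1$training_trace, m2$training_trace)
  tr <- m1$training_trace
  expect_lt(tr$total[nrow(tr)], tr$total[1])
  # loss decomposition identity at every epoch
  w <- cfg$task_loss_weights
  expect_equal(tr$total,
               w[1] * tr$reconstruction + w[2] * tr$propensity +
                 w[3] * tr$missing_pattern,
               tolerance = 1e-12)
  # non-convergence in few epochs warns
  expect_warning(mtnn_train(d, mtnn_config(max_epochs = 3, seed = 1)),
                 "convergence")
})

test_that("untrained zero-headed model predicts 0.5 and imputes the mean", {
  d <- impose_missingness(make_sim_data(100, 0, seed = 35),
                          missingness_spec("MCAR", 0.4), seed = 1)
  m0 <- mtnn_init(d, mtnn_config(seed = 2))
  expect_true(all(predict_propensity(m0, d)$scores == 0.5))
  imp <- mtnn_impute(m0, d)
  mis <- d$mask[, "X2"] == 1
  obs_mean <- mean(d$covariates[!mis, "X2"])
  expect_equal(unname(imp[mis, "X2"]), rep(obs_mean, sum(mis)),
               tolerance = 1e-12)
  expect_identical(imp[!mis, "X2"], d$covariates[!mis, "X2"])
})

test_that("pure propensity task tracks logistic regression on complete data", {
  d <- make_sim_data(1e4, 0, seed = 37)
  cfg <- mtnn_config(task_loss_weights = c(0, 1, 0), seed = 3)
  m <- suppressWarnings(mtnn_train(d, cfg))
  ps <- predict_propensity(m, d)$scores
  glm_ps <- fitted(glm(d$treatment ~ d$covariates, family = binomial))
  expect_gt(cor(ps, glm_ps), 0.99)
  # calibration in the mean: mean score ~ treated fraction
  expect_lt(abs(mean(ps) - mean(d$treatment)), 0.02)
  expect_true(all(ps > 0 & ps < 1))
})

test_that("imputation beats the marginal-mean baseline under MAR", {
  full <- make_sim_data(1e4, 0, seed = 39)
  d <- impose_missingness(full, missingness_spec("MAR", 0.5), seed = 2)
  m <- mtnn_train(d, mtnn_config(seed = 4))
  imp <- mtnn_impute(m, d)
  mis <- d$mask[, "X2"] == 1
  rmse <- sqrt(mean((imp[mis, "X2"] - d$truth[mis, "X2"])^2))
  expect_lt(rmse, 1)  # marginal-mean imputation has RMSE ~ sd(X2) = 1
  expect_identical(imp[!mis, "X2"], d$covariates[!mis, "X2"])
  # no missing entries -> identity
  imp_full <- mtnn_impute(mtnn_init(full, mtnn_config(seed = 1)), full)
  expect_equal(unclass(imp_full), unclass(full$covariates),
               ignore_attr = TRUE)
})

test_that("reconstruction loss depends on observed cells only", {
  d <- make_tiny_masked()
  d2 <- d
  d2$truth[2, 2] <- 99  # perturb a masked cell's stored true value
  cfg <- mtnn_config(max_epochs = 20, seed = 5)
  t1 <- suppressWarnings(mtnn_train(d, cfg))$training_trace
  t2 <- suppressWarnings(mtnn_train(d2, cfg))$training_trace
  expect_identical(t1, t2)
})

test_that("checkpoints and trace export round-trip", {
  d <- impose_missingness(make_sim_data(120, 0, seed = 41),
                          missingness_spec("MCAR", 0.3), seed = 1)
  m <- suppressWarnings(mtnn_train(d, mtnn_config(max_epochs = 30, seed = 6)))
  path <- tempfile(fileext = ".json")
  save_mtnn(m, path)
  back <- load_mtnn(path)
  expect_equal(predict_propensity(back, d)$scores,
               predict_propensity(m, d)$scores, tolerance = 1e-12)
  expect_equal(back$training_trace$total, m$training_trace$total,
               tolerance = 1e-12)
  csv <- tempfile(fileext = ".csv")
  write_training_trace(m, csv)
  expect_equal(nrow(read.csv(csv)), nrow(m$training_trace))
  unlink(c(path, csv))
  # config validation
  expect_error(mtnn_config(task_loss_weights = c(1, 0, 1)), "propensity")
  expect_error(mtnn_config(hidden_layer_sizes = integer()), "hidden")
  expect_error(predict_propensity(m, make_tiny_masked_renamed()), "layout")
})
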