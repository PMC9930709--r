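# shared fixtures and independent oracles

# small simulated complete dataset
make_sim_data <- function(n = 400, effect = 0, seed = 11) {
  simulate_scenario(scenario_spec(n, effect, seed = seed))
}

# tiny hand-built dataset with one masked cell in X2
make_tiny_masked <- function() {
  x <- covariate_matrix(cbind(X1 = c(-1, 0, 0.5, 1, 2, -0.5),
                              X2 = c(0.2, NA, 0.1, 1.2, 0.8, NA)))
  observed_dataset(x, treatment = c(0, 1, 0, 1, 1, 0),
                   outcome = c(0.1, 1.4, -0.2, 2.5, 2.2, -0.6),
                   truth = cbind(c(-1, 0, 0.5, 1, 2, -0.5),
                                 c(0.2, 0.4, 0.1, 1.2, 0.8, -0.3)))
}

# brute-force logistic likelihood maximizer over a refined grid:
# independent oracle for intercept+slope models on tiny instances
grid_logistic <- function(x, t) {
  loglik <- function(b0, b1) {
    eta <- b0 + b1 * x
    sum(t * eta - log1p(exp(eta)))
  }
  lo <- c(-5, -5); hi <- c(5, 5)
  best <- c(0, 0)
  for (pass in 1:4) {
    b0s <- seq(lo[1], hi[1], length.out = 41)
    b1s <- seq(lo[2], hi[2], length.out = 41)
    ll <- outer(b0s, b1s, Vectorize(loglik))
    ix <- which(ll == max(ll), arr.ind = TRUE)[1, ]
    best <- c(b0s[ix[1]], b1s[ix[2]])
    step <- c(b0s[2] - b0s[1], b1s[2] - b1s[1])
    lo <- best - 2 * step
    hi <- best + 2 * step
  }
  best
}

# 1-D bisection for the missingness offset: independent of calibrate_offset
bisect_offset <- function(drivers, rate) {
  f <- function(C) mean(1 / (1 + exp(-(drivers + C)))) - rate
  lo <- -30; hi <- 30
  for (i in 1:200) {
    mid <- (lo + hi) / 2
    if (f(mid) > 0) hi <- mid else lo <- mid
  }
  (lo + hi) / 2
}

# observed-only center/scale computed independently of the package internals
fit_standardization_for_test <- function(d) {
  K <- ncol(d$covariates)
  center <- scale <- numeric(K)
  for (j in seq_len(K)) {
    obs <- d$covariates[d$mask[, j] == 0, j]
    center[j] <- mean(obs)
    scale[j] <- sd(obs)
  }
  list(center = center, scale = scale)
}

# same tiny dataset with different column names (layout-mismatch probe)
make_tiny_masked_renamed <- function() {
  d <- make_tiny_masked()
  x <- d$covariates
  colnames(x) <- c("A", "B")
  observed_dataset(covariate_matrix(x, c("A", "B")), d$treatment, d$outcome)
}
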