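#' Monte Carlo experiment grid
#'
#' The evaluation design: scenario (true effect) x missingness mechanism x
#' missing rate x method, each cell repeated `repetitions` times. The source
#' study runs 20,000 repetitions per cell; the package default of 2000 is a
#' desk-scale stand-in (full scale is just a config change).
#'
#' @param true_effects numeric vector of scenario effects (default `c(0, 1)`).
#' @param mechanisms subset of `c("MCAR","MAR","MNAR")`.
#' @param rates missing rates (default `seq(0.2, 0.8, 0.1)`).
#' @param methods subset of
#'   `c("missing_indicator","multiple_imputation","mtnn")`.
#' @param repetitions per-cell repetitions (>= 2).
#' @param base_seed integer; repetition r uses seed `base_seed + r`.
#' @param n_subjects per-dataset sample size.
#' @param adjust_covariates include the (method-specific, completed)
#'   covariates in the weighted effect regression. See the methods vignette
#'   for why this is the default.
#' @param mice_m,mice_iterations multiple-imputation settings.
#' @param mtnn an [mtnn_config()] template (its `seed` is ignored; each
#'   repetition trains inside the repetition's seeded RNG stream).
#' @return An object of class `experiment_grid`.
#' @export
experiment_grid <- function(true_effects = c(0, 1),
                            mechanisms = c("MCAR", "MAR", "MNAR"),
                            rates = seq(0.2, 0.8, by = 0.1),
                            methods = c("missing_indicator",
                                        "multiple_imputation", "mtnn"),
                            repetitions = 2000, base_seed = 1L,
                            n_subjects = 1000, adjust_covariates = TRUE,
                            mice_m = 5, mice_iterations = 5,
                            mtnn = mtnn_config()) {
  stopifnot(length(true_effects) >= 1, length(mechanisms) >= 1,
            length(rates) >= 1, length(methods) >= 1, repetitions >= 2)
  mechanisms <- match.arg(mechanisms, c("MCAR", "MAR", "MNAR"),
                          several.ok = TRUE)
  methods <- match.arg(methods,
                       c("missing_indicator", "multiple_imputation", "mtnn",
                         "complete_data"), several.ok = TRUE)
  if (base_seed + repetitions >= 2^31) stop("base_seed too large")
  structure(list(true_effects = true_effects, mechanisms = mechanisms,
                 rates = rates, methods = methods,
                 repetitions = as.integer(repetitions),
                 base_seed = as.integer(base_seed),
                 n_subjects = as.integer(n_subjects),
                 adjust_covariates = adjust_covariates,
                 mice_m = mice_m, mice_iterations = mice_iterations,
                 mtnn = mtnn),
            class = "experiment_grid")
}

default_cell_options <- function() {
  list(adjust_covariates = TRUE, mice_m = 5, mice_iterations = 5,
       mtnn = mtnn_config())
}

# one masked dataset -> one effect estimate, per method
estimate_effect_for_method <- function(masked, method, opts) {
  adj <- isTRUE(opts$adjust_covariates)
  switch(method,
    missing_indicator = {
      fit <- missing_indicator_ps(masked)
      w <- ipw_weights(fit$propensity, masked$treatment)
      weighted_effect(masked$outcome, masked$treatment, fit$design, w,
                      include_covariates = adj,
                      method_label = "missing_indicator")$beta_hat
    },
    multiple_imputation = {
      imps <- mice_impute(masked, m = opts$mice_m,
                          chain_iterations = opts$mice_iterations)
      mi_pooled_effect(imps, masked$treatment, masked$outcome,
                       ipw_effect_estimator(include_covariates = adj))
    },
    mtnn = {
      cfg <- opts$mtnn
      cfg$seed <- NULL  # train inside the repetition's RNG stream
      model <- mtnn_train(masked, cfg)
      w <- ipw_weights(predict_propensity(model, masked), masked$treatment)
      cov <- if (adj) mtnn_impute(model, masked) else NULL
      weighted_effect(masked$outcome, masked$treatment, cov, w,
                      include_covariates = adj,
                      method_label = "mtnn")$beta_hat
    },
    complete_data = {
      cov <- if (!is.null(masked$truth)) masked$truth else masked$covariates
      if (anyNA(cov)) stop("complete_data method needs complete covariates")
      ipw_effect_estimator(include_covariates = adj)(
        cov, masked$treatment, masked$outcome)
    },
    stop("unknown method: ", method))
}

#' Run one grid cell
#'
#' For repetition r (seed `base_seed + r`): generate a dataset under the
#' scenario, impose missingness, run the method's propensity (+ imputation)
#' pipeline, and estimate the IPW effect. All methods given the same seed see
#' the identical masked dataset. Failing repetitions are dropped and counted;
#' the result is flagged when more than 1% fail.
#'
#' @param scenario a [scenario_spec()] (its `seed` field is ignored here).
#' @param mechanism,rate missingness mechanism and target rate.
#' @param method one of the grid methods.
#' @param repetitions number of repetitions.
#' @param base_seed integer seed base.
#' @param options list of pipeline options (see [experiment_grid()] fields);
#'   missing entries take defaults.
#' @return numeric vector of effect estimates with attributes `n_failed`
#'   and `flagged`.
#' @export
run_cell <- function(scenario, mechanism, rate, method, repetitions,
                     base_seed, options = list()) {
  stopifnot(inherits(scenario, "scenario_spec"))
  if (!method %in% c("missing_indicator", "multiple_imputation", "mtnn",
                     "complete_data")) {
    stop("unknown method: ", method)
  }
  opts <- utils::modifyList(default_cell_options(), options)
  if (base_seed + repetitions >= 2^31) stop("base_seed too large")
  mspec <- missingness_spec(mechanism, rate)
  est <- rep(NA_real_, repetitions)
  for (r in seq_len(repetitions)) {
    set.seed(base_seed + r)
    est[r] <- tryCatch({
      sc <- scenario
      sc$seed <- NULL
      full <- simulate_scenario(sc)
      masked <- suppressWarnings(impose_missingness(full, mspec))
      suppressWarnings(estimate_effect_for_method(masked, method, opts))
    }, error = function(e) NA_real_)
  }
  n_failed <- sum(is.na(est))
  out <- est[!is.na(est)]
  attr(out, "n_failed") <- n_failed
  attr(out, "flagged") <- n_failed > 0.01 * repetitions
  out
}

#' Summarize effect estimates
#'
#' Mean, sample SD, and `RMSE = sqrt(mean((beta_hat - beta)^2))` against the
#' true effect.
#'
#' @param estimates numeric vector (>= 2 values).
#' @param true_effect the true (or reference) effect beta.
#' @return named numeric vector `c(mean, sd, rmse)`.
#' @export
summarize_estimates <- function(estimates, true_effect) {
  estimates <- as.numeric(estimates)
  if (length(estimates) < 2) stop("need at least two estimates")
  c(mean = mean(estimates), sd = stats::sd(estimates),
    rmse = sqrt(mean((estimates - true_effect)^2)))
}

#' Reproduce the simulation metrics table
#'
#' Runs every cell of the grid and returns the metrics in the study's table
#' layout: rate-major, method-minor rows, one (mean, SD, RMSE) triple per
#' scenario. Cell failure flags are propagated.
#'
#' @param grid an [experiment_grid()].
#' @param csv_path optional path; when given the long-format table is also
#'   written as CSV (one row per mechanism x rate x method x scenario --
#'   the RMSE-vs-rate series for curve plots is a subset of these rows).
#' @param verbose print progress lines.
#' @return data.frame of class `metrics_table`.
#' @export
reproduce_table <- function(grid, csv_path = NULL, verbose = FALSE) {
  stopifnot(inherits(grid, "experiment_grid"))
  opts <- list(adjust_covariates = grid$adjust_covariates,
               mice_m = grid$mice_m, mice_iterations = grid$mice_iterations,
               mtnn = grid$mtnn)
  rows <- list()
  for (mech in grid$mechanisms) {
    for (rate in grid$rates) {
      for (method in grid$methods) {
        for (eff in grid$true_effects) {
          est <- run_cell(scenario_spec(grid$n_subjects, eff),
                          mech, rate, method, grid$repetitions,
                          grid$base_seed, opts)
          s <- summarize_estimates(est, eff)
          rows[[length(rows) + 1]] <- data.frame(
            mechanism = mech, rate = rate, method = method,
            true_effect = eff, mean = s["mean"], sd = s["sd"],
            rmse = s["rmse"], n_successes = length(est),
            flagged = attr(est, "flagged"), row.names = NULL)
          if (verbose) {
            message(sprintf("%s rate=%.1f %s effect=%g: mean=%.3f rmse=%.3f",
                            mech, rate, method, eff, s["mean"], s["rmse"]))
          }
        }
      }
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("metrics_table", "data.frame")
  if (!is.null(csv_path)) utils::write.csv(out, csv_path, row.names = FALSE)
  out
}
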