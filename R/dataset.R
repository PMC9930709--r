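#' Covariate matrix with column typing
#'
#' A plain numeric matrix whose columns are labelled and flagged as binary or
#' continuous. Binary columns must contain only 0/1 where observed.
#'
#' @param values numeric n x K matrix (may contain `NA` for missing cells).
#' @param names optional character vector of K column labels.
#' @param is_binary logical vector of length K (default all continuous).
#' @return The matrix with a `is_binary` attribute and column names set.
#' @export
covariate_matrix <- function(values, names = colnames(values),
                             is_binary = rep(FALSE, ncol(values))) {
  values <- as.matrix(values)
  if (ncol(values) < 1L) stop("at least one covariate is required")
  if (is.null(names)) names <- paste0("X", seq_len(ncol(values)))
  if (length(names) != ncol(values)) stop("names must have one entry per column")
  if (length(is_binary) != ncol(values)) stop("is_binary must have one entry per column")
  storage.mode(values) <- "double"
  colnames(values) <- names
  for (j in which(is_binary)) {
    obs <- values[!is.na(values[, j]), j]
    if (length(obs) && !all(obs %in% c(0, 1))) {
      stop("binary column '", names[j], "' contains values outside {0,1}")
    }
  }
  attr(values, "is_binary") <- as.logical(is_binary)
  values
}

is_binary_cols <- function(x) {
  b <- attr(x, "is_binary")
  if (is.null(b)) rep(FALSE, ncol(x)) else b
}

#' Observed dataset: covariates, missingness mask, treatment and outcome
#'
#' The central container. Missing covariate cells are `NA` in `covariates`
#' and flagged 1 in `mask`. Treatment and outcome are always fully observed.
#' When the dataset was produced by masking a complete dataset, the pre-mask
#' values may be carried in `truth`; estimation code never reads them -- they
#' exist only so test oracles can score imputations.
#'
#' @param covariates numeric matrix (see [covariate_matrix()]), `NA` = missing.
#' @param treatment integer/numeric vector of 0/1 treatment indicators.
#' @param outcome numeric outcome vector.
#' @param mask optional 0/1 matrix (1 = missing); derived from `NA` pattern
#'   when omitted.
#' @param truth optional complete covariate matrix of pre-mask values.
#' @return An object of class `observed_dataset`.
#' @export
observed_dataset <- function(covariates, treatment, outcome, mask = NULL,
                             truth = NULL) {
  covariates <- covariate_matrix(covariates,
                                 is_binary = is_binary_cols(covariates))
  n <- nrow(covariates)
  treatment <- as.numeric(treatment)
  outcome <- as.numeric(outcome)
  if (length(treatment) != n || length(outcome) != n) {
    stop("treatment and outcome must match the covariate row count")
  }
  if (anyNA(treatment) || anyNA(outcome)) {
    stop("treatment and outcome must be fully observed")
  }
  if (!all(treatment %in% c(0, 1))) stop("treatment must be binary 0/1")
  if (sum(treatment) == 0 || sum(treatment) == n) {
    stop("need at least one treated and one control subject")
  }
  derived <- matrix(as.numeric(is.na(covariates)), n, ncol(covariates),
                    dimnames = dimnames(covariates))
  if (is.null(mask)) {
    mask <- derived
  } else {
    mask <- as.matrix(mask)
    if (!identical(dim(mask), dim(covariates))) stop("mask shape mismatch")
    if (!all(mask %in% c(0, 1))) stop("mask entries must be 0/1")
    if (!all(mask == derived)) stop("mask disagrees with the NA pattern")
  }
  if (!is.null(truth)) {
    truth <- as.matrix(truth)
    if (!identical(dim(truth), dim(covariates)) || anyNA(truth)) {
      stop("truth must be a complete matrix of the same shape")
    }
  }
  structure(list(covariates = covariates, mask = mask,
                 treatment = treatment, outcome = outcome, truth = truth),
            class = "observed_dataset")
}

#' @export
print.observed_dataset <- function(x, ...) {
  n_mis <- sum(x$mask)
  cat("<observed_dataset> n =", nrow(x$covariates),
      "| K =", ncol(x$covariates),
      "| treated =", sum(x$treatment),
      "| missing cells =", n_mis,
      sprintf("(%.1f%%)\n", 100 * n_mis / length(x$mask)))
  invisible(x)
}

n_subjects <- function(data) nrow(data$covariates)

#' Write / read a dataset as CSV with a JSON sidecar
#'
#' Covariates, treatment and outcome go into one CSV (missing cells as empty
#' fields). Generation metadata (scenario / missingness specs, seed) is kept
#' in `<path>.json`.
#'
#' @param data an [observed_dataset()].
#' @param path CSV file path.
#' @param meta optional list of metadata to store in the sidecar.
#' @return `path`, invisibly.
#' @export
write_dataset_csv <- function(data, path, meta = list()) {
  df <- as.data.frame(data$covariates)
  df$treatment <- data$treatment
  df$outcome <- data$outcome
  utils::write.csv(df, path, row.names = FALSE, na = "")
  meta$is_binary <- is_binary_cols(data$covariates)
  meta$covariates <- colnames(data$covariates)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_dataset_csv
#' @export
read_dataset_csv <- function(path) {
  df <- utils::read.csv(path)
  side <- paste0(path, ".json")
  meta <- if (file.exists(side)) jsonlite::read_json(side, simplifyVector = TRUE) else list()
  cov_names <- meta$covariates
  if (is.null(cov_names)) cov_names <- setdiff(names(df), c("treatment", "outcome"))
  is_bin <- meta$is_binary
  if (is.null(is_bin)) is_bin <- rep(FALSE, length(cov_names))
  cov <- covariate_matrix(as.matrix(df[cov_names]), cov_names, is_bin)
  observed_dataset(cov, df$treatment, df$outcome)
}
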