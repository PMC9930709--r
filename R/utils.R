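#' @keywords internal
"_PACKAGE"

# numerically safe inverse logit
expit <- function(x) 1 / (1 + exp(-x))

# clip probabilities away from {0,1}; guards IPW arithmetic only
clip_prob <- function(p, eps = 1e-6) pmin(pmax(p, eps), 1 - eps)

#' Per-subject propensity scores
#'
#' Light container pairing a score vector with the label of the method that
#' produced it. Scores are clipped to `[eps, 1 - eps]` so downstream inverse
#' probability weights are always finite.
#'
#' @param scores numeric vector of probabilities.
#' @param method_label character scalar naming the producing method.
#' @param eps clipping constant (default `1e-6`).
#' @return An object of class `propensity_result`.
#' @export
propensity_result <- function(scores, method_label = "unknown", eps = 1e-6) {
  scores <- as.numeric(scores)
  if (anyNA(scores) || any(!is.finite(scores))) {
    stop("propensity scores must be finite and non-missing")
  }
  if (any(scores < 0) || any(scores > 1)) {
    stop("propensity scores must lie in [0, 1] before clipping")
  }
  structure(list(scores = clip_prob(scores, eps), method_label = method_label),
            class = "propensity_result")
}

#' @export
print.propensity_result <- function(x, ...) {
  cat("<propensity_result>", x$method_label, "- n =", length(x$scores),
      "- mean score =", signif(mean(x$scores), 4), "\n")
  invisible(x)
}

as_scores <- function(x) {
  if (inherits(x, "propensity_result")) x$scores else as.numeric(x)
}

check_seed <- function(seed) {
  if (is.null(seed)) return(invisible(NULL))
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
    stop("seed must be a single finite number")
  }
  if (abs(seed) >= 2^31) stop("seed must fit in a 32-bit integer")
  set.seed(as.integer(seed))
  invisible(seed)
}
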