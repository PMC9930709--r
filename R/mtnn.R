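#' Multi-task network configuration
#'
#' Architecture and training settings for the shared-trunk, three-head
#' network (covariate reconstruction, propensity score, missing-pattern
#' prediction). Defaults: two hidden layers of width `max(8, 4K)` with ReLU,
#' equal task weights, Adam at learning rate 1e-2, at most 500 epochs with
#' early stopping once the relative change of the epoch total loss over a
#' 10-epoch window falls below 1e-4 ("the last epoch after convergence"),
#' full batch for n <= 4096 and mini-batches of 256 beyond that.
#'
#' During training, observed input cells are additionally corrupted
#' (zero-filled with their mask input flipped on) with per-column probability
#' `corruption_rate`; the reconstruction and mask-prediction losses are
#' computed on the corrupted pass while the propensity loss uses a clean
#' pass. Without this denoising step the reconstruction head learns the
#' identity on observed cells and cannot impute. `corruption_rate = NULL`
#' uses the per-column empirical missing rate clamped to [0.1, 0.5].
#'
#' @param hidden_layer_sizes integer vector; `NULL` = `rep(max(8, 4K), 2)`.
#' @param activation `"relu"` or `"tanh"`.
#' @param task_loss_weights length-3 non-negative weights
#'   (reconstruction, propensity, missing pattern); propensity weight > 0.
#' @param learning_rate Adam step size.
#' @param max_epochs maximum training epochs.
#' @param convergence_tol relative-change tolerance for early stopping.
#' @param convergence_window epochs over which the change is measured.
#' @param batch_size `"full"` (auto: full batch up to n = 4096, else 256)
#'   or a positive integer.
#' @param corruption_rate `NULL` (auto) or per-column corruption probability.
#' @param seed RNG seed for initialization, corruption and batching.
#' @return An object of class `mtnn_config`.
#' @export
mtnn_config <- function(hidden_layer_sizes = NULL, activation = c("relu", "tanh"),
                        task_loss_weights = c(1, 1, 1), learning_rate = 1e-2,
                        max_epochs = 500, convergence_tol = 1e-4,
                        convergence_window = 10, batch_size = "full",
                        corruption_rate = NULL, seed = 1L) {
  activation <- match.arg(activation)
  if (!is.null(hidden_layer_sizes)) {
    if (!length(hidden_layer_sizes) || any(hidden_layer_sizes < 1)) {
      stop("need at least one hidden layer of positive width")
    }
  }
  w <- as.numeric(task_loss_weights)
  if (length(w) != 3 || any(w < 0) || all(w == 0)) {
    stop("task_loss_weights must be 3 non-negative reals, not all zero")
  }
  if (w[2] <= 0) stop("the propensity task weight must be positive")
  if (learning_rate <= 0 || max_epochs < 1 || convergence_tol <= 0 ||
      convergence_window < 1) {
    stop("invalid training configuration")
  }
  structure(list(hidden_layer_sizes = hidden_layer_sizes,
                 activation = activation, task_loss_weights = w,
                 learning_rate = learning_rate,
                 max_epochs = as.integer(max_epochs),
                 convergence_tol = convergence_tol,
                 convergence_window = as.integer(convergence_window),
                 batch_size = batch_size, corruption_rate = corruption_rate,
                 seed = seed),
            class = "mtnn_config")
}

# per-column center/scale from observed entries only; binary columns pass
# through untouched (center 0, scale 1)
fit_standardization <- function(data) {
  x <- data$covariates
  bin <- is_binary_cols(x)
  center <- scale <- numeric(ncol(x))
  for (j in seq_len(ncol(x))) {
    obs <- x[data$mask[, j] == 0, j]
    if (!length(obs)) stop("column '", colnames(x)[j], "' is entirely missing")
    if (bin[j]) {
      center[j] <- 0; scale[j] <- 1
    } else {
      center[j] <- mean(obs)
      s <- stats::sd(obs)
      scale[j] <- if (is.na(s) || s == 0) 1 else s
    }
  }
  list(center = center, scale = scale, is_binary = bin,
       columns = colnames(x))
}

standardize_values <- function(x, std) {
  sweep(sweep(x, 2, std$center, "-"), 2, std$scale, "/")
}

#' Encode a dataset as network input
#'
#' Continuous columns are standardized (observed-entry center/scale), missing
#' entries are zero-filled (the post-standardization mean), and the K-column
#' mask is concatenated as additional inputs, giving an n x 2K matrix.
#'
#' @param data an [observed_dataset()].
#' @param standardization output of the internal standardization fit; when
#'   `NULL` it is fitted from `data`.
#' @return numeric n x 2K matrix.
#' @export
encode_inputs <- function(data, standardization = NULL) {
  if (is.null(standardization)) standardization <- fit_standardization(data)
  x <- data$covariates
  x[is.na(x)] <- 0
  xs <- standardize_values(x, standardization) * (1 - data$mask)
  colnames(xs) <- standardization$columns
  m <- data$mask
  colnames(m) <- paste0("miss_", standardization$columns)
  cbind(xs, m)
}

act_fun <- function(name) {
  switch(name,
         relu = list(f = function(x) (x + abs(x)) / 2, df = function(z) z > 0),
         tanh = list(f = base::tanh, df = function(z) 1 - tanh(z)^2))
}

mtnn_params_init <- function(D, H, K) {
  he <- function(r, c) matrix(stats::rnorm(r * c, sd = sqrt(2 / r)), r, c)
  sizes <- c(D, H)
  trunk <- list()
  for (l in seq_along(H)) {
    trunk[[paste0("W", l)]] <- he(sizes[l], sizes[l + 1])
    trunk[[paste0("b", l)]] <- rep(0, sizes[l + 1])
  }
  Hl <- H[length(H)]
  heads <- list(Wr = matrix(0, Hl, K), br = rep(0, K),
                wp = matrix(0, Hl, 1), bp = 0,
                Wm = matrix(0, Hl, K), bm = rep(0, K))
  c(trunk, heads)
}

# forward through the trunk; returns activations and pre-activations
trunk_forward <- function(P, A0, n_layers, act) {
  Z <- A <- vector("list", n_layers)
  a <- A0
  for (l in seq_len(n_layers)) {
    z <- a %*% P[[paste0("W", l)]]
    z <- z + rep(P[[paste0("b", l)]], each = nrow(z))
    Z[[l]] <- z
    a <- act$f(z)
    A[[l]] <- a
  }
  list(Z = Z, A = A, top = a)
}

# backward from a gradient at the trunk top; returns trunk parameter grads
trunk_backward <- function(P, A0, fw, dTop, n_layers, act) {
  G <- list()
  d <- dTop
  for (l in rev(seq_len(n_layers))) {
    dZ <- d * act$df(fw$Z[[l]])
    below <- if (l == 1) A0 else fw$A[[l - 1]]
    G[[paste0("W", l)]] <- crossprod(below, dZ)
    G[[paste0("b", l)]] <- colSums(dZ)
    if (l > 1) d <- tcrossprod(dZ, P[[paste0("W", l)]])
  }
  G
}

safe_log <- function(p) log(pmax(p, 1e-12))

# cross-entropy of probabilities q against 0/1 targets t, optionally
# restricted by a 0/1 weight matrix
xent <- function(q, t) -(t * safe_log(q) + (1 - t) * safe_log(1 - q))

# the three task losses given head outputs on the standardized scale
task_losses <- function(recon, prop, maskpred, xstd, obs, mask_target,
                        is_binary, treatment) {
  cont <- !is_binary
  l_rec <- 0
  if (any(cont)) {
    oc <- obs[, cont, drop = FALSE]
    ncc <- sum(oc)
    if (ncc > 0) {
      l_rec <- l_rec + sum(oc * (recon[, cont, drop = FALSE] -
                                 xstd[, cont, drop = FALSE])^2) / ncc
    }
  }
  if (any(is_binary)) {
    ob <- obs[, is_binary, drop = FALSE]
    nb <- sum(ob)
    if (nb > 0) {
      qb <- expit(recon[, is_binary, drop = FALSE])
      l_rec <- l_rec + sum(ob * xent(qb, xstd[, is_binary, drop = FALSE])) / nb
    }
  }
  l_prop <- mean(xent(prop, treatment))
  l_mask <- mean(xent(maskpred, mask_target))
  c(reconstruction = l_rec, propensity = l_prop, missing_pattern = l_mask)
}

#' Joint loss of the three tasks
#'
#' `total = w1 * (MSE over observed continuous cells + mean cross-entropy
#' over observed binary cells) + w2 * cross-entropy(propensity, T) +
#' w3 * per-cell cross-entropy(mask prediction, M)`. The reconstruction term
#' is computed over *observed* cells only; continuous reconstructions are
#' compared on the standardized scale.
#'
#' @param outputs list with elements `reconstruction` (n x K, standardized
#'   scale; logits for binary columns), `propensity` (n probabilities) and
#'   `missing_pattern` (n x K probabilities).
#' @param data an [observed_dataset()].
#' @param weights length-3 task weights.
#' @param standardization optional; fitted from `data` when `NULL`.
#' @return list with `total` and `per_task` (length-3 named vector).
#' @export
mtnn_joint_loss <- function(outputs, data, weights = c(1, 1, 1),
                            standardization = NULL) {
  if (is.null(standardization)) standardization <- fit_standardization(data)
  x <- data$covariates
  x[is.na(x)] <- 0
  xstd <- standardize_values(x, standardization)
  recon <- as.matrix(outputs$reconstruction)
  prop <- as.numeric(outputs$propensity)
  mp <- as.matrix(outputs$missing_pattern)
  if (!identical(dim(recon), dim(x)) || length(prop) != nrow(x) ||
      !identical(dim(mp), dim(x))) {
    stop("output shapes do not match the dataset")
  }
  if (any(!is.finite(recon)) || any(!is.finite(prop)) || any(!is.finite(mp))) {
    stop("non-finite network output")
  }
  per <- task_losses(recon, prop, mp, xstd, obs = 1 - data$mask,
                     mask_target = data$mask,
                     is_binary = standardization$is_binary,
                     treatment = data$treatment)
  list(total = sum(weights * per), per_task = per)
}

#' Initialize an untrained multi-task network
#'
#' Trunk weights use He initialization under the config seed; all head
#' weights start at zero, so the untrained propensity head outputs 0.5
#' everywhere and the reconstruction head outputs the (standardized) column
#' means.
#'
#' @param data an [observed_dataset()] (fixes the column layout and
#'   standardization).
#' @param config an [mtnn_config()].
#' @return An object of class `mtnn_model` with an empty training trace.
#' @export
mtnn_init <- function(data, config = mtnn_config()) {
  std <- fit_standardization(data)
  K <- ncol(data$covariates)
  H <- config$hidden_layer_sizes
  if (is.null(H)) H <- rep(max(8, 4 * K), 2)
  check_seed(config$seed)
  params <- mtnn_params_init(2 * K, H, K)
  structure(list(config = config, standardization = std,
                 hidden_layer_sizes = H, params = params,
                 training_trace = data.frame(epoch = integer(),
                                             total = numeric(),
                                             reconstruction = numeric(),
                                             propensity = numeric(),
                                             missing_pattern = numeric()),
                 converged = FALSE),
            class = "mtnn_model")
}

#' @export
print.mtnn_model <- function(x, ...) {
  cat("<mtnn_model> trunk", paste(x$hidden_layer_sizes, collapse = "-"),
      "| K =", length(x$standardization$columns),
      "| epochs trained =", nrow(x$training_trace),
      "| converged =", x$converged, "\n")
  invisible(x)
}

#' Train the multi-task network
#'
#' Jointly minimizes the weighted three-task loss with Adam. Each epoch runs
#' two forward passes: a corrupted pass feeding the reconstruction and
#' mask-prediction losses (denoising; targets are the effective mask and the
#' observed standardized values) and a clean pass feeding the propensity
#' loss, so the propensity head trains on the same input distribution it
#' predicts on. Training stops at `max_epochs` or when the relative change
#' of total loss over `convergence_window` epochs drops below
#' `convergence_tol`; the returned model is the final epoch's parameters.
#'
#' @param data an [observed_dataset()] containing both treatment groups.
#' @param config an [mtnn_config()].
#' @return A trained `mtnn_model` with a per-epoch `training_trace`
#'   (columns: epoch, total, reconstruction, propensity, missing_pattern).
#' @export
mtnn_train <- function(data, config = mtnn_config()) {
  model <- mtnn_init(data, config)
  std <- model$standardization
  P <- model$params
  act <- act_fun(config$activation)
  nL <- length(model$hidden_layer_sizes)
  n <- n_subjects(data); K <- ncol(data$covariates)
  w <- config$task_loss_weights

  x <- data$covariates
  x[is.na(x)] <- 0
  xstd <- standardize_values(x, std)
  mask <- data$mask
  obs <- 1 - mask
  bin <- std$is_binary
  tr_vec <- data$treatment
  A0_clean <- cbind(xstd * obs, mask)

  corrupt <- config$corruption_rate
  if (is.null(corrupt)) corrupt <- pmin(pmax(colMeans(mask), 0.1), 0.5)
  corrupt <- rep_len(corrupt, K)

  bs <- config$batch_size
  if (identical(bs, "full")) bs <- if (n <= 4096) n else 256L
  bs <- min(as.integer(bs), n)

  adam_m <- lapply(P, function(p) p * 0)
  adam_v <- adam_m
  lr <- config$learning_rate
  b1 <- 0.9; b2 <- 0.999; adam_eps <- 1e-8; step <- 0L

  trace <- matrix(NA_real_, config$max_epochs, 4)
  epochs_run <- 0L
  for (e in seq_len(config$max_epochs)) {
    Bc <- matrix(stats::rbinom(n * K, 1, rep(corrupt, each = n)), n, K) * obs
    Meff <- pmax(mask, Bc)
    A0_cor <- cbind(xstd * (1 - Meff), Meff)
    ord <- if (bs < n) sample.int(n) else seq_len(n)
    starts <- seq(1, n, by = bs)
    epoch_loss <- c(0, 0, 0)
    for (s in starts) {
      idx <- ord[s:min(s + bs - 1, n)]
      nb <- length(idx)
      a0c <- A0_cor[idx, , drop = FALSE]
      a0p <- A0_clean[idx, , drop = FALSE]
      fc <- trunk_forward(P, a0c, nL, act)
      fp <- trunk_forward(P, a0p, nL, act)
      recon <- fc$top %*% P$Wr + rep(P$br, each = nb)
      Q <- expit(fc$top %*% P$Wm + rep(P$bm, each = nb))
      p <- expit(drop(fp$top %*% P$wp) + P$bp)
      per <- task_losses(recon, p, Q,
                         xstd[idx, , drop = FALSE], obs[idx, , drop = FALSE],
                         Meff[idx, , drop = FALSE], bin, tr_vec[idx])
      if (any(!is.finite(per))) {
        stop("training diverged (non-finite loss) at epoch ", e,
             "; trace so far: ",
             paste(signif(stats::na.omit(trace[, 1]), 4), collapse = ", "))
      }
      epoch_loss <- epoch_loss + per * nb / n

      # gradients at head pre-activations
      ob <- obs[idx, , drop = FALSE]
      dR <- matrix(0, nb, K)
      cont <- !bin
      if (any(cont)) {
        oc <- ob[, cont, drop = FALSE]
        ncc <- sum(oc)
        if (ncc > 0) {
          dR[, cont] <- w[1] * 2 * oc *
            (recon[, cont, drop = FALSE] - xstd[idx, cont, drop = FALSE]) / ncc
        }
      }
      if (any(bin)) {
        obb <- ob[, bin, drop = FALSE]
        nbb <- sum(obb)
        if (nbb > 0) {
          dR[, bin] <- w[1] * obb *
            (expit(recon[, bin, drop = FALSE]) -
               xstd[idx, bin, drop = FALSE]) / nbb
        }
      }
      dzp <- w[2] * (p - tr_vec[idx]) / nb
      dZm <- w[3] * (Q - Meff[idx, , drop = FALSE]) / (nb * K)

      dTop_c <- tcrossprod(dR, P$Wr) + tcrossprod(dZm, P$Wm)
      dTop_p <- outer(dzp, drop(P$wp))
      Gc <- trunk_backward(P, a0c, fc, dTop_c, nL, act)
      Gp <- trunk_backward(P, a0p, fp, dTop_p, nL, act)
      G <- Gc
      for (k in names(Gp)) G[[k]] <- G[[k]] + Gp[[k]]
      G$Wr <- crossprod(fc$top, dR);  G$br <- colSums(dR)
      G$wp <- crossprod(fp$top, dzp); G$bp <- sum(dzp)
      G$Wm <- crossprod(fc$top, dZm); G$bm <- colSums(dZm)

      step <- step + 1L
      c1 <- 1 - b1^step; c2 <- 1 - b2^step
      for (k in names(P)) {
        adam_m[[k]] <- b1 * adam_m[[k]] + (1 - b1) * G[[k]]
        adam_v[[k]] <- b2 * adam_v[[k]] + (1 - b2) * G[[k]]^2
        P[[k]] <- P[[k]] - lr * (adam_m[[k]] / c1) /
          (sqrt(adam_v[[k]] / c2) + adam_eps)
      }
    }
    trace[e, ] <- c(sum(w * epoch_loss), epoch_loss)
    epochs_run <- e
    win <- config$convergence_window
    if (e > win) {
      prev <- trace[e - win, 1]
      if (abs(prev - trace[e, 1]) <
          config$convergence_tol * max(abs(prev), 1e-8) * win) {
        model$converged <- TRUE
        break
      }
    }
  }
  if (!model$converged) {
    warning("mtnn_train: convergence window criterion not met within ",
            config$max_epochs, " epochs; returning the final model")
  }
  model$params <- P
  model$training_trace <- data.frame(epoch = seq_len(epochs_run),
                                     total = trace[seq_len(epochs_run), 1],
                                     reconstruction = trace[seq_len(epochs_run), 2],
                                     propensity = trace[seq_len(epochs_run), 3],
                                     missing_pattern = trace[seq_len(epochs_run), 4])
  model
}

mtnn_forward_heads <- function(model, data) {
  std <- model$standardization
  if (!identical(colnames(data$covariates), std$columns)) {
    stop("dataset columns do not match the model's training layout")
  }
  A0 <- encode_inputs(data, std)
  act <- act_fun(model$config$activation)
  fw <- trunk_forward(model$params, A0, length(model$hidden_layer_sizes), act)
  n <- nrow(A0)
  list(recon = fw$top %*% model$params$Wr + rep(model$params$br, each = n),
       prop = expit(drop(fw$top %*% model$params$wp) + model$params$bp),
       maskpred = expit(fw$top %*% model$params$Wm +
                          rep(model$params$bm, each = n)))
}

#' Propensity scores from a trained network
#'
#' @param model a trained `mtnn_model`.
#' @param data an [observed_dataset()] with the training column layout.
#' @return A [propensity_result()] (scores clipped to `[1e-6, 1 - 1e-6]`).
#' @export
predict_propensity <- function(model, data) {
  stopifnot(inherits(model, "mtnn_model"))
  propensity_result(mtnn_forward_heads(model, data)$prop, "mtnn")
}

#' Impute missing covariates with the reconstruction head
#'
#' Observed entries pass through unchanged; missing entries are replaced by
#' the reconstruction head's output de-standardized to the original scale
#' (binary columns: the head's probability).
#'
#' @param model a trained `mtnn_model`.
#' @param data an [observed_dataset()].
#' @return A complete covariate matrix.
#' @export
mtnn_impute <- function(model, data) {
  stopifnot(inherits(model, "mtnn_model"))
  std <- model$standardization
  recon <- mtnn_forward_heads(model, data)$recon
  bin <- std$is_binary
  if (any(bin)) recon[, bin] <- expit(recon[, bin, drop = FALSE])
  recon <- sweep(sweep(recon, 2, std$scale, "*"), 2, std$center, "+")
  out <- data$covariates
  out[data$mask == 1] <- recon[data$mask == 1]
  covariate_matrix(out, std$columns, bin)
}

#' Save / load a model checkpoint (single JSON file)
#'
#' @param model an `mtnn_model`.
#' @param path file path.
#' @return `path` (save) or the restored model (load).
#' @export
save_mtnn <- function(model, path) {
  ser <- list(config = unclass(model$config),
              hidden_layer_sizes = model$hidden_layer_sizes,
              standardization = model$standardization,
              converged = model$converged,
              training_trace = model$training_trace,
              params = lapply(model$params, function(p) {
                if (is.matrix(p)) list(dim = dim(p), values = as.numeric(p))
                else list(dim = NULL, values = as.numeric(p))
              }))
  jsonlite::write_json(ser, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname save_mtnn
#' @export
load_mtnn <- function(path) {
  ser <- jsonlite::read_json(path, simplifyVector = TRUE)
  cfg <- ser$config
  config <- mtnn_config(hidden_layer_sizes = cfg$hidden_layer_sizes,
                        activation = cfg$activation,
                        task_loss_weights = cfg$task_loss_weights,
                        learning_rate = cfg$learning_rate,
                        max_epochs = cfg$max_epochs,
                        convergence_tol = cfg$convergence_tol,
                        convergence_window = cfg$convergence_window,
                        batch_size = cfg$batch_size,
                        corruption_rate = cfg$corruption_rate,
                        seed = cfg$seed)
  params <- lapply(ser$params, function(p) {
    if (!is.null(p$dim) && length(p$dim)) matrix(p$values, p$dim[1], p$dim[2])
    else if (length(p$values) == 1) p$values else as.numeric(p$values)
  })
  std <- ser$standardization
  std$is_binary <- as.logical(std$is_binary)
  structure(list(config = config, standardization = std,
                 hidden_layer_sizes = ser$hidden_layer_sizes,
                 params = params,
                 training_trace = as.data.frame(ser$training_trace),
                 converged = isTRUE(ser$converged)),
            class = "mtnn_model")
}

#' Export the training trace as CSV
#'
#' Columns: epoch, total, reconstruction, propensity, missing_pattern.
#'
#' @param model an `mtnn_model`.
#' @param path CSV path.
#' @export
write_training_trace <- function(model, path) {
  utils::write.csv(model$training_trace, path, row.names = FALSE)
  invisible(path)
}
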