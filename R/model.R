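#' Hyperparameters for a single imputation model
#'
#' @param n_protein_factors Number of protein embedding factors `p`.
#' @param n_sample_factors Number of sample embedding factors `q`.
#' @param n_hidden_layers Number of hidden layers in the MLP.
#' @param nodes_per_layer Nodes per hidden layer.
#' @param learning_rate Adam learning rate (default 0.001).
#' @param batch_size Training batch size (default 128).
#' @param leaky_slope Negative slope of the leaky-ReLU activations (default
#'   0.1).
#' @param tol Relative-improvement tolerance of stopping criterion 1 (default
#'   0.001).
#' @param patience Successive low-improvement epochs required by criterion 1
#'   (default 10).
#' @param max_epochs Hard cap on training epochs (default 500; the stopping
#'   criteria normally fire long before).
#' @param p_bg Background acceptance probability of the biased batch sampler
#'   (default 0.35; 1 gives unbiased sampling).
#' @return An object of class `hyperparams`.
#' @export
hyperparams <- function(n_protein_factors, n_sample_factors,
                        n_hidden_layers, nodes_per_layer,
                        learning_rate = 0.001, batch_size = 128,
                        leaky_slope = 0.1, tol = 0.001, patience = 10,
                        max_epochs = 500, p_bg = 0.35) {
  stopifnot(n_protein_factors > 0, n_sample_factors > 0,
            n_hidden_layers > 0, nodes_per_layer > 0, learning_rate > 0)
  structure(list(n_protein_factors = as.integer(n_protein_factors),
                 n_sample_factors = as.integer(n_sample_factors),
                 n_hidden_layers = as.integer(n_hidden_layers),
                 nodes_per_layer = as.integer(nodes_per_layer),
                 learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 leaky_slope = leaky_slope, tol = tol,
                 patience = as.integer(patience),
                 max_epochs = as.integer(max_epochs),
                 p_bg = p_bg),
            class = "hyperparams")
}

#' @export
print.hyperparams <- function(x, ...) {
  cat(sprintf("hyperparams: p=%d q=%d, %d hidden layer(s) x %d nodes\n",
              x$n_protein_factors, x$n_sample_factors,
              x$n_hidden_layers, x$nodes_per_layer))
  invisible(x)
}

runif_mat <- function(nr, nc, bound) {
  matrix(stats::runif(nr * nc, -bound, bound), nr, nc)
}

#' Initialize protein/sample embeddings and MLP weights
#'
#' All parameters are drawn uniformly in plus/minus `1/sqrt(fan_in)`, the
#' standard linear-layer initialization: entries of the protein factor matrix
#' `W` (n x p) are bounded by `1/sqrt(p)`, entries of the sample factor matrix
#' `H` (q x m) by `1/sqrt(q)`, and each MLP layer by the reciprocal square
#' root of its input width. The MLP input width is `p + q` (the concatenated
#' factor pair) and the output width is 1.
#'
#' @param n Number of proteins (rows).
#' @param m Number of samples (columns).
#' @param hp A [hyperparams] object.
#' @param seed Integer seed; the same seed gives a bit-identical state.
#' @return An object of class `model_state` with elements `W`, `H`, `mlp`
#'   (list of `list(weight, bias)` per layer), `hp`, and `seed`.
#' @export
init_model <- function(n, m, hp, seed = 1L) {
  stopifnot(n > 0, m > 0, inherits(hp, "hyperparams"))
  p <- hp$n_protein_factors
  q <- hp$n_sample_factors
  widths <- c(p + q, rep(hp$nodes_per_layer, hp$n_hidden_layers), 1L)
  with_seed(seed, {
    W <- runif_mat(n, p, 1 / sqrt(p))
    H <- runif_mat(q, m, 1 / sqrt(q))
    mlp <- vector("list", length(widths) - 1L)
    for (l in seq_along(mlp)) {
      fan_in <- widths[l]
      bound <- 1 / sqrt(fan_in)
      mlp[[l]] <- list(weight = runif_mat(widths[l + 1L], fan_in, bound),
                       bias = stats::runif(widths[l + 1L], -bound, bound))
    }
    structure(list(W = W, H = H, mlp = mlp, hp = hp, seed = seed),
              class = "model_state")
  })
}

#' @export
print.model_state <- function(x, ...) {
  cat(sprintf("model_state: W %d x %d, H %d x %d, %d MLP layer(s)\n",
              nrow(x$W), ncol(x$W), nrow(x$H), ncol(x$H), length(x$mlp)))
  invisible(x)
}

#' Predict intensities for (protein, sample) index pairs
#'
#' The protein factor row `W[i, ]` and sample factor column `H[, j]` are
#' concatenated and passed through the MLP, with leaky-ReLU after every hidden
#' layer and no activation after the final scalar output. Implemented in plain
#' R matrix arithmetic; the compiled prediction path ([predict_all()]) must
#' agree with it exactly.
#'
#' @param state A `model_state`.
#' @param i Protein row indices (1-based), recycled against `j`.
#' @param j Sample column indices (1-based).
#' @return Numeric vector of predictions, one per (i, j) pair.
#' @export
forward <- function(state, i, j) {
  n <- nrow(state$W); m <- ncol(state$H)
  if (any(i < 1 | i > n) || any(j < 1 | j > m)) {
    stop("index out of range")
  }
  k <- max(length(i), length(j))
  i <- rep_len(i, k); j <- rep_len(j, k)
  slope <- state$hp$leaky_slope
  A <- cbind(state$W[i, , drop = FALSE], t(state$H)[j, , drop = FALSE])
  nl <- length(state$mlp)
  for (l in seq_len(nl)) {
    Z <- A %*% t(state$mlp[[l]]$weight)
    Z <- sweep(Z, 2L, state$mlp[[l]]$bias, "+")
    A <- if (l < nl) pmax(Z, 0) + slope * pmin(Z, 0) else Z
  }
  as.numeric(A)
}

#' Dense reconstruction of the full matrix
#'
#' @param state A `model_state`.
#' @return An n x m numeric matrix with no missing entries, where entry
#'   `(i, j)` equals `forward(state, i, j)`.
#' @export
predict_all <- function(state) {
  weights <- lapply(state$mlp, `[[`, "weight")
  biases <- lapply(state$mlp, `[[`, "bias")
  cpp_predict_all(state$W, state$H, weights, biases, state$hp$leaky_slope)
}

#' Early-stopping decision from a validation-loss trace
#'
#' Two stopping criteria are evaluated on the per-epoch validation MSE trace:
#'
#' 1. *Tolerance plateau.* At each epoch the ratio of (best loss so far minus
#'    current loss) to the best loss so far is computed, using the best loss
#'    over strictly earlier epochs. If this ratio stays below `tol` for
#'    `patience` successive epochs, training stops. Negative ratios (current
#'    loss worse than the best) count as below `tol`.
#' 2. *Wilcoxon windows.* Once at least 15 epochs have run, a one-sided
#'    Wilcoxon rank-sum test compares the losses of epochs `n-14 ... n-10`
#'    (the older window) against the previous five epochs `n-4 ... n`; if the
#'    older window is significantly smaller (p < 0.05, normal approximation
#'    with continuity correction), validation error has stopped decreasing and
#'    started to rise, and training stops.
#'
#' @param trace Numeric vector of validation MSEs, one per epoch.
#' @param tol Relative-improvement tolerance (default 0.001).
#' @param patience Successive epochs below tolerance required (default 10).
#' @return `list(stop = logical, reason = "tolerance" | "wilcoxon" | "none")`.
#' @export
convergence_check <- function(trace, tol = 0.001, patience = 10) {
  n <- length(trace)
  if (n >= patience + 1) {
    best_before <- cummin(c(Inf, trace))[seq_len(n)]
    ratio <- ifelse(!is.finite(best_before), Inf,
             ifelse(best_before > 0,
                    (best_before - trace) / best_before, 0))
    recent <- ratio[(n - patience + 1):n]
    if (all(recent < tol)) {
      return(list(stop = TRUE, reason = "tolerance"))
    }
  }
  if (n >= 15) {
    w2 <- trace[(n - 14):(n - 10)]
    w1 <- trace[(n - 4):n]
    p <- suppressWarnings(
      stats::wilcox.test(w2, w1, alternative = "less",
                         exact = FALSE, correct = TRUE)$p.value)
    if (!is.na(p) && p < 0.05) {
      return(list(stop = TRUE, reason = "wilcoxon"))
    }
  }
  list(stop = FALSE, reason = "none")
}

#' Train a single imputation model
#'
#' Minimizes the mean squared error between observed training entries and MLP
#' predictions with Adam. Each epoch draws `ceil(n_train / batch_size)` biased
#' batches (see [biased_batches()] for the sampling scheme; the same
#' thresholds/Bernoulli machinery is applied here, with the threshold
#' distribution computed from the present values of `X`), takes one optimizer
#' step per batch, then evaluates the MSE on the held-out validation entries
#' and consults [convergence_check()]. Validation entries never contribute a
#' gradient. Embedding tables are updated with sparse Adam steps (only rows
#' and columns appearing in the batch advance); MLP weights take dense steps.
#'
#' @param X A [quant_matrix].
#' @param mask A `partition_mask` for `X` containing train and validation
#'   entries (test entries, if any, are never touched).
#' @param hp A [hyperparams] object.
#' @param seed Integer seed; identical seeds and inputs give identical traces
#'   and parameters.
#' @param rollback_best If `TRUE`, return the parameters of the epoch with the
#'   lowest validation MSE instead of the final epoch (default `FALSE`).
#' @return `list(state = model_state, trace = training_trace)` where the trace
#'   holds `val_mse_by_epoch`, `stop_reason` (`"tolerance"`, `"wilcoxon"`, or
#'   `"max_epochs"`), and `epochs_run`.
#' @export
train_model <- function(X, mask, hp, seed = 1L, rollback_best = FALSE) {
  stopifnot_quant_matrix(X)
  stopifnot_partition_mask(mask, X)
  stopifnot(inherits(hp, "hyperparams"))
  v <- X$values
  tr <- mask_entries(mask, "train")
  va <- mask_entries(mask, "validation")
  if (length(tr) == 0) stop("mask has no train entries")
  if (length(va) == 0) stop("mask has no validation entries (convergence undefined)")
  nr <- nrow(v)
  # batch-bias thresholds come from the training entries only: held-out
  # validation/test values must not influence any parameter update
  pars <- threshold_params_values(v[tr])
  state0 <- init_model(nr, ncol(v), hp, seed = seed)
  weights <- lapply(state0$mlp, `[[`, "weight")
  biases <- lapply(state0$mlp, `[[`, "bias")
  conv_fun <- function(trace) convergence_check(trace, hp$tol, hp$patience)
  fit <- with_seed(seed, {
    cpp_train(state0$W, state0$H, weights, biases,
              v[tr], as.integer((tr - 1L) %% nr), as.integer((tr - 1L) %/% nr),
              v[va], as.integer((va - 1L) %% nr), as.integer((va - 1L) %/% nr),
              hp$learning_rate, hp$batch_size, hp$max_epochs, hp$leaky_slope,
              pars$mu, pars$sd, hp$p_bg, rollback_best, conv_fun)
  })
  mlp <- Map(function(w, b) list(weight = w, bias = as.numeric(b)),
             fit$weights, fit$biases)
  state <- structure(list(W = fit$W, H = fit$H, mlp = mlp, hp = hp,
                          seed = seed),
                     class = "model_state")
  dimnames(state$W) <- list(rownames(v), NULL)
  dimnames(state$H) <- list(NULL, colnames(v))
  trace <- structure(list(val_mse_by_epoch = as.numeric(fit$trace),
                          stop_reason = fit$stop_reason,
                          epochs_run = fit$epochs),
                     class = "training_trace")
  list(state = state, trace = trace)
}

#' @export
print.training_trace <- function(x, ...) {
  cat(sprintf("training_trace: %d epochs, stopped by %s, final val MSE %.4g\n",
              x$epochs_run, x$stop_reason,
              x$val_mse_by_epoch[x$epochs_run]))
  invisible(x)
}

#' Save / load a model checkpoint
#'
#' The checkpoint holds the embeddings, MLP arrays, hyperparameters, and seed,
#' and round-trips exactly.
#'
#' @param state A `model_state`.
#' @param path File path (RDS format).
#' @return `save_model` returns `path` invisibly; `load_model` returns the
#'   `model_state`.
#' @export
save_model <- function(state, path) {
  stopifnot(inherits(state, "model_state"))
  saveRDS(state, path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  state <- readRDS(path)
  stopifnot(inherits(state, "model_state"))
  state
}
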