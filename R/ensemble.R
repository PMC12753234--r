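#' Hyperparameter grids
#'
#' `default_grid()` is the full search space used for large joint matrices:
#' protein and sample factor counts in \{64, 128, 256, 512, 1024\}, hidden
#' layers in \{1, 2, 4\}, and nodes per hidden layer in \{512, 1024, 2048\} —
#' 225 combinations in total. `reduced_grid()` is a preset for matrices of a
#' few thousand proteins: factor counts in \{32, 64\}, hidden layers in
#' \{1, 2\}, and nodes in \{64, 128\}. The reduced grid keeps the model in
#' the same overparameterized regime relative to the matrix as the full grid
#' (factor counts comparable to the number of samples), which is a defining
#' characteristic of the method, while remaining tractable on a single CPU.
#'
#' @return A data frame with columns `p`, `q`, `hidden_layers`, `nodes`, one
#'   row per combination.
#' @export
default_grid <- function() {
  expand.grid(p = c(64L, 128L, 256L, 512L, 1024L),
              q = c(64L, 128L, 256L, 512L, 1024L),
              hidden_layers = c(1L, 2L, 4L),
              nodes = c(512L, 1024L, 2048L))
}

#' @rdname default_grid
#' @export
reduced_grid <- function() {
  expand.grid(p = c(32L, 64L),
              q = c(32L, 64L),
              hidden_layers = c(1L, 2L),
              nodes = c(64L, 128L))
}

#' Sample distinct hyperparameter combinations from a grid
#'
#' Draws `n_models` distinct rows uniformly without replacement, deterministic
#' given `seed` and independent of any matrix contents.
#'
#' @param n_models Number of combinations to draw.
#' @param grid A grid data frame, see [default_grid()].
#' @param seed Integer seed.
#' @param ... Further arguments (e.g. `max_epochs`, `batch_size`, `p_bg`)
#'   passed to [hyperparams()] for every member.
#' @return A list of [hyperparams] objects.
#' @export
sample_hyperparams <- function(n_models = 10, grid = default_grid(),
                               seed = 1L, ...) {
  if (n_models > nrow(grid)) {
    stop(sprintf("n_models (%d) exceeds the grid size (%d)",
                 n_models, nrow(grid)))
  }
  rows <- with_seed(seed, sample(nrow(grid), n_models))
  lapply(rows, function(r) {
    hyperparams(n_protein_factors = grid$p[r],
                n_sample_factors = grid$q[r],
                n_hidden_layers = grid$hidden_layers[r],
                nodes_per_layer = grid$nodes[r], ...)
  })
}

#' Ensemble imputation
#'
#' Fits `n_models` independent models, each with a hyperparameter combination
#' sampled from the grid, its own seed (`base_seed + k` for member `k`), and
#' its own MCAR validation split (`val_frac` of the training entries), then
#' averages their dense reconstructions element-wise. The averaged
#' reconstruction fills the missing entries; observed entries keep their
#' original values in the imputed matrix. Members are summed in member order,
#' so the result is bit-reproducible given the seeds.
#'
#' @param X A [quant_matrix].
#' @param mask Optional `partition_mask`; when supplied, only its
#'   train-labelled entries are training candidates (test entries stay
#'   hidden). When omitted, every present entry is a training candidate.
#' @param n_models Ensemble size (default 10).
#' @param grid Hyperparameter grid (default [default_grid()]).
#' @param base_seed Integer seed; also seeds the grid sampling.
#' @param val_frac MCAR validation fraction per member (default 0.10).
#' @param keep_members Keep per-member states and prediction matrices
#'   (memory-hungry; default `FALSE`).
#' @param ... Passed to [hyperparams()] for every member (e.g. `max_epochs`).
#' @return An object of class `imputation_result`: list with `reconstructed`
#'   (dense n x m matrix, the member mean), `imputed` (a [quant_matrix] with
#'   no missing values: observed entries as in `X`, missing entries from the
#'   reconstruction), `member_traces`, `member_hyperparams`, and — when
#'   `keep_members = TRUE` — `member_states` and `member_predictions`.
#' @export
ensemble_impute <- function(X, mask = NULL, n_models = 10,
                            grid = default_grid(), base_seed = 1L,
                            val_frac = 0.10, keep_members = FALSE, ...) {
  stopifnot_quant_matrix(X)
  hps <- sample_hyperparams(n_models, grid, seed = base_seed, ...)
  v <- X$values
  base_labels <- if (is.null(mask)) {
    lab <- matrix(NA_integer_, nrow(v), ncol(v), dimnames = dimnames(v))
    lab[!is.na(v)] <- 1L
    lab
  } else {
    stopifnot_partition_mask(mask, X)
    mask$labels
  }
  train_pool <- which(base_labels == 1L)
  if (length(train_pool) == 0) stop("no training entries available")
  acc <- NULL
  traces <- vector("list", n_models)
  states <- if (keep_members) vector("list", n_models) else NULL
  preds <- if (keep_members) vector("list", n_models) else NULL
  for (k in seq_len(n_models)) {
    member_seed <- base_seed + k
    labels_k <- base_labels
    labels_k[labels_k == 2L] <- 1L # any pre-existing validation rejoins train
    n_val <- round(val_frac * length(train_pool))
    if (n_val == 0) stop("val_frac too small: empty validation set")
    val_k <- with_seed(member_seed, sample(train_pool, n_val))
    labels_k[val_k] <- 2L
    mask_k <- new_partition_mask(labels_k, member_seed,
                                 list(scheme = "ensemble_member",
                                      val_frac = val_frac))
    fit <- train_model(X, mask_k, hps[[k]], seed = member_seed)
    pred_k <- predict_all(fit$state)
    acc <- if (is.null(acc)) pred_k else acc + pred_k
    traces[[k]] <- fit$trace
    if (keep_members) {
      states[[k]] <- fit$state
      preds[[k]] <- pred_k
    }
  }
  reconstructed <- acc / n_models
  dimnames(reconstructed) <- dimnames(v)
  imputed_vals <- v
  miss <- is.na(v)
  imputed_vals[miss] <- reconstructed[miss]
  out <- list(reconstructed = reconstructed,
              imputed = quant_matrix(imputed_vals, X$dataset),
              member_traces = traces,
              member_hyperparams = hps)
  if (keep_members) {
    out$member_states <- states
    out$member_predictions <- preds
  }
  structure(out, class = "imputation_result")
}

#' @export
print.imputation_result <- function(x, ...) {
  cat(sprintf("imputation_result: %d member(s), %d x %d reconstruction\n",
              length(x$member_traces),
              nrow(x$reconstructed), ncol(x$reconstructed)))
  invisible(x)
}

#' Export a model's embeddings as TSV
#'
#' Writes the protein factors `W` (proteins x factors) and sample factors `H`
#' transposed (samples x factors) with their IDs, for downstream analyses such
#' as low-dimensional visualisation. Embeddings are per-member quantities and
#' are not identifiable across ensemble members.
#'
#' @param state A `model_state` (e.g. from `member_states` of an
#'   [ensemble_impute()] run with `keep_members = TRUE`).
#' @param prefix Output path prefix; `<prefix>_W.tsv` and `<prefix>_H.tsv` are
#'   written.
#' @return Invisibly, the two paths.
#' @export
export_embeddings <- function(state, prefix) {
  stopifnot(inherits(state, "model_state"))
  pw <- paste0(prefix, "_W.tsv")
  ph <- paste0(prefix, "_H.tsv")
  dfw <- data.frame(id = rownames(state$W) %||% seq_len(nrow(state$W)),
                    state$W, check.names = FALSE)
  hmat <- t(state$H)
  dfh <- data.frame(id = rownames(hmat) %||% seq_len(nrow(hmat)),
                    hmat, check.names = FALSE)
  utils::write.table(dfw, pw, sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(dfh, ph, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(pw, ph))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
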