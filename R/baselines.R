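#' k-nearest-neighbour imputation
#'
#' Observations are samples (columns) and features are proteins (rows).
#' Distances between samples use the NaN-aware Euclidean convention: the
#' squared distance over mutually present proteins is rescaled by
#' `n_proteins / n_shared` before the square root, so samples sharing few
#' proteins are not artificially close. A missing entry `(i, j)` is imputed as
#' the unweighted mean of the values of protein `i` in the `k` nearest samples
#' that have protein `i` present (samples lacking it fall back to the next
#' nearest); when no neighbour has the protein, the protein's overall mean is
#' used.
#'
#' @param X A [quant_matrix]; every protein must have at least one present
#'   value.
#' @param k Number of neighbours (default 5).
#' @return A dense numeric matrix; observed entries are returned unchanged.
#' @export
knn_impute <- function(X, k = 5) {
  stopifnot_quant_matrix(X)
  if (k < 1) stop("`k` must be at least 1")
  v <- X$values
  if (!any(is.na(v))) return(v)
  if (any(rowSums(!is.na(v)) == 0)) {
    stop("every protein must have at least one present value")
  }
  n <- nrow(v); m <- ncol(v)
  M <- !is.na(v)
  A <- v; A[!M] <- 0
  Mn <- matrix(as.numeric(M), n, m)
  SQ <- crossprod(A^2, Mn)                 # [j, j'] = sum_{shared} x_ij^2
  n_shared <- crossprod(Mn)
  D2 <- SQ + t(SQ) - 2 * crossprod(A)
  D2[D2 < 0] <- 0                          # numerical noise
  dist <- sqrt(D2 * n / pmax(n_shared, 1))
  dist[n_shared == 0] <- Inf
  diag(dist) <- Inf
  row_means <- rowSums(A) / rowSums(Mn)
  out <- v
  for (j in seq_len(m)) {
    miss_i <- which(!M[, j])
    if (length(miss_i) == 0) next
    ord <- order(dist[, j])
    ord <- ord[is.finite(dist[ord, j])]
    for (i in miss_i) {
      donors <- ord[M[i, ord]]
      if (length(donors) == 0) {
        out[i, j] <- row_means[i]
      } else {
        use <- donors[seq_len(min(k, length(donors)))]
        out[i, j] <- mean(v[i, use])
      }
    }
  }
  out
}

#' Gaussian down-shift imputation
#'
#' Replicates the random-sampling procedure popularised by the Perseus
#' platform: missing entries in a sample are drawn from a Gaussian whose mean
#' is shifted `shift` standard deviations below the sample's observed mean and
#' whose standard deviation is `width` times the sample's observed standard
#' deviation, mimicking left-censored MNAR dropout. By construction the
#' imputed distribution sits to the left of the observed one.
#'
#' @param X A [quant_matrix].
#' @param width Width of the imputation distribution relative to the observed
#'   standard deviation (default 0.3).
#' @param shift Down-shift in observed standard deviations (default 1.8).
#' @param per_sample If `TRUE` (default), moments are computed per sample
#'   column; otherwise from all present values globally.
#' @param seed Integer seed.
#' @return A dense numeric matrix; observed entries are returned unchanged.
#' @export
gaussian_downshift_impute <- function(X, width = 0.3, shift = 1.8,
                                      per_sample = TRUE, seed = 1L) {
  stopifnot_quant_matrix(X)
  v <- X$values
  pres_all <- v[!is.na(v)]
  if (length(pres_all) < 2) stop("need at least 2 present values")
  g_mu <- mean(pres_all)
  g_sd <- stats::sd(pres_all)
  out <- v
  with_seed(seed, {
    for (j in seq_len(ncol(v))) {
      miss <- which(is.na(v[, j]))
      if (length(miss) == 0) next
      if (per_sample) {
        pres <- v[!is.na(v[, j]), j]
        if (length(pres) < 2) stop(sprintf(
          "sample %s has fewer than 2 present values", colnames(v)[j]))
        mu <- mean(pres)
        s <- stats::sd(pres)
        if (s == 0) {
          warning(sprintf(
            "sample %s has zero variance; falling back to global sd",
            colnames(v)[j]))
          s <- g_sd
        }
      } else {
        mu <- g_mu
        s <- g_sd
      }
      out[miss, j] <- stats::rnorm(length(miss),
                                   mean = mu - shift * s, sd = width * s)
    }
  })
  out
}

#' Test-set reconstruction error
#'
#' @param pred Dense prediction matrix, same shape as `X`.
#' @param X A [quant_matrix] holding the ground-truth values.
#' @param mask A `partition_mask` with at least one test entry.
#' @return An `eval_report`: list with `test_mse` (mean squared error over
#'   test-labelled entries only), `n_test_entries`, and
#'   `per_protein_residuals` (named vector of mean absolute residuals per
#'   protein, over that protein's test entries; proteins without test entries
#'   are omitted).
#' @export
test_mse <- function(pred, X, mask) {
  stopifnot_quant_matrix(X)
  stopifnot_partition_mask(mask, X)
  if (!identical(dim(pred), dim(X$values))) stop("pred shape mismatch")
  te <- mask_entries(mask, "test")
  if (length(te) == 0) stop("mask has no test entries")
  resid <- pred[te] - X$values[te]
  rows <- ((te - 1L) %% nrow(X$values)) + 1L
  per_protein <- tapply(abs(resid), rownames(X$values)[rows], mean)
  structure(list(test_mse = mean(resid^2),
                 n_test_entries = length(te),
                 per_protein_residuals = per_protein[protein_ids(X)[
                   protein_ids(X) %in% names(per_protein)]]),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("eval_report: test MSE %.4f over %d test entries (%d proteins)\n",
              x$test_mse, x$n_test_entries, length(x$per_protein_residuals)))
  invisible(x)
}

#' Fraction of proteins predicted more accurately by method A
#'
#' Restricted to proteins where either method's residual exceeds `min_resid`,
#' so that proteins both methods predict near-perfectly do not dilute the
#' comparison. Ties count as half.
#'
#' @param residA,residB Named numeric vectors of per-protein residuals over
#'   the same protein universe (e.g. `per_protein_residuals` from
#'   [test_mse()]).
#' @param min_resid Eligibility cutoff on `max(residA, residB)` (default
#'   0.25, strict `>`).
#' @return The fraction of eligible proteins with `residA < residB`; `NaN`
#'   with a warning when no protein is eligible.
#' @export
frac_more_accurate <- function(residA, residB, min_resid = 0.25) {
  if (!is.null(names(residA)) && !is.null(names(residB))) {
    common <- intersect(names(residA), names(residB))
    if (length(common) != length(residA) || length(common) != length(residB)) {
      stop("residual vectors cover different protein universes")
    }
    residB <- residB[names(residA)]
  } else if (length(residA) != length(residB)) {
    stop("residual vectors cover different protein universes")
  }
  eligible <- pmax(residA, residB) > min_resid
  eligible[is.na(eligible)] <- FALSE
  if (!any(eligible)) {
    warning("no protein exceeds the residual cutoff; returning NaN")
    return(NaN)
  }
  a <- residA[eligible]
  b <- residB[eligible]
  (sum(a < b) + 0.5 * sum(a == b)) / sum(eligible)
}
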