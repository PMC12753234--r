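# Run code with a temporary RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = genv)
    else if (exists(".Random.seed", envir = genv, inherits = FALSE)) {
      rm(".Random.seed", envir = genv)
    }
  })
  set.seed(seed)
  force(code)
}

new_partition_mask <- function(labels, seed, params) {
  structure(list(labels = labels, seed = seed, params = params),
            class = "partition_mask")
}

stopifnot_partition_mask <- function(mask, X = NULL) {
  if (!inherits(mask, "partition_mask")) stop("expected a `partition_mask`")
  if (!is.null(X) && !identical(dim(mask$labels), dim(X$values))) {
    stop("mask and matrix dimensions differ")
  }
  invisible(mask)
}

#' @export
print.partition_mask <- function(x, ...) {
  tab <- tabulate(x$labels, nbins = 3L)
  cat(sprintf("partition_mask: %d train / %d validation / %d test (seed %s)\n",
              tab[1], tab[2], tab[3], format(x$seed)))
  invisible(x)
}

#' Linear indices of entries carrying a given partition label
#'
#' @param mask A `partition_mask`.
#' @param label One of `"train"`, `"validation"`, `"test"`.
#' @return Integer vector of column-major linear indices into the matrix the
#'   mask was built for.
#' @export
mask_entries <- function(mask, label = c("train", "validation", "test")) {
  label <- match.arg(label)
  code <- match(label, c("train", "validation", "test"))
  which(mask$labels == code)
}

#' Draw a thresholds matrix for MNAR partitioning
#'
#' The thresholds matrix `T` is a dense matrix, congruent with `X`, of i.i.d.
#' Gaussian draws centred on a low percentile of the present values of `X`
#' (default the 25th) with standard deviation `sd_scale` times the sample
#' standard deviation of the present values. Entries falling below their
#' threshold are candidates for censoring, which is what makes the resulting
#' held-out sets left-shifted: low-intensity values are more likely to sit
#' below their threshold.
#'
#' @param X A [quant_matrix] with at least two present entries.
#' @param percentile Percentile (0-100) of present values used as the Gaussian
#'   mean; default 25.
#' @param sd_scale Multiplier on the sample standard deviation of present
#'   values; default 1.1.
#' @param seed Integer seed.
#' @return A numeric matrix of thresholds, same shape as `X$values`, fully
#'   dense.
#' @export
make_thresholds <- function(X, percentile = 25, sd_scale = 1.1, seed = 1L) {
  stopifnot_quant_matrix(X)
  pars <- threshold_params(X, percentile, sd_scale)
  v <- X$values
  with_seed(seed, {
    matrix(stats::rnorm(length(v), mean = pars$mu, sd = pars$sd),
           nrow = nrow(v), dimnames = dimnames(v))
  })
}

# Gaussian parameters of the thresholds distribution for X.
threshold_params <- function(X, percentile = 25, sd_scale = 1.1) {
  threshold_params_values(X$values[!is.na(X$values)], percentile, sd_scale)
}

threshold_params_values <- function(pres, percentile = 25, sd_scale = 1.1) {
  if (length(pres) == 0) stop("all entries of X are missing")
  if (length(pres) < 2) stop("X must have at least 2 present entries")
  mu <- unname(stats::quantile(pres, percentile / 100))
  sd <- sd_scale * stats::sd(pres)
  list(mu = mu, sd = sd)
}

#' MNAR train/validation/test partition via a thresholds matrix
#'
#' Every present entry is assigned exactly one label. An entry whose value
#' exceeds its threshold draw goes to the training set; otherwise a Bernoulli
#' trial with success probability `bernoulli_p` sends it to the test set
#' (success) or back to the training set (failure). Because low values are
#' more likely to fall below their thresholds, the test set is left-shifted:
#' its mean is below the training-set mean, mimicking the preferential dropout
#' of low-abundance proteins in mass-spectrometry data. Optionally a further
#' MCAR fraction of the training entries is relabelled as validation.
#'
#' The default `bernoulli_p = 0.61` was tuned for a large pan-cancer TMT
#' matrix to yield a 20 percent test fraction; other matrices should use
#' [calibrate_bernoulli_p()].
#'
#' @param X A [quant_matrix] with present entries.
#' @param bernoulli_p Probability that a below-threshold entry is assigned to
#'   the test set.
#' @param percentile,sd_scale Thresholds-matrix parameters, see
#'   [make_thresholds()].
#' @param val_frac MCAR fraction of training entries relabelled validation
#'   (default 0).
#' @param seed Integer seed; identical inputs and seed give identical masks.
#' @return A `partition_mask`.
#' @export
mnar_partition <- function(X, bernoulli_p = 0.61, percentile = 25,
                           sd_scale = 1.1, val_frac = 0, seed = 1L) {
  stopifnot_quant_matrix(X)
  v <- X$values
  present <- which(!is.na(v))
  if (length(present) == 0) stop("X has no present entries")
  pars <- threshold_params(X, percentile, sd_scale)
  labels <- matrix(NA_integer_, nrow(v), ncol(v), dimnames = dimnames(v))
  with_seed(seed, {
    thr <- stats::rnorm(length(present), mean = pars$mu, sd = pars$sd)
    x <- v[present]
    lab <- rep(1L, length(present))
    below <- thr >= x
    n_below <- sum(below)
    if (n_below > 0) {
      hit <- stats::runif(n_below) < bernoulli_p
      lab[below][hit] <- 3L
    }
    if (val_frac > 0) {
      tr <- which(lab == 1L)
      n_val <- round(val_frac * length(tr))
      if (n_val > 0) lab[sample(tr, n_val)] <- 2L
    }
    labels[present] <- lab
  })
  tr_mean <- mean(v[labels == 1L], na.rm = TRUE)
  te <- v[!is.na(labels) & labels == 3L]
  if (length(te) > 0 && !(mean(te) < tr_mean)) {
    warning("MNAR partition did not produce a left-shifted test set ",
            "(mean(test) >= mean(train)); input may be degenerate")
  }
  new_partition_mask(labels, seed,
                     list(scheme = "mnar", bernoulli_p = bernoulli_p,
                          percentile = percentile, sd_scale = sd_scale,
                          val_frac = val_frac))
}

#' Calibrate the Bernoulli probability for a target test fraction
#'
#' Under the thresholds-matrix partition, the expected test fraction is
#' `p * mean(P(T >= X_ij))` over present entries, which is linear in `p`, so
#' the calibration is solved in closed form from the Gaussian threshold
#' distribution. An error is raised when the target exceeds the achievable
#' range (the mean censoring probability at `p = 1`).
#'
#' @param X A [quant_matrix].
#' @param target_test_frac Desired expected test fraction, in (0, 1), or 0.
#' @param percentile,sd_scale Thresholds-matrix parameters.
#' @return The calibrated Bernoulli probability, a single number in \[0, 1\].
#' @export
calibrate_bernoulli_p <- function(X, target_test_frac = 0.2,
                                  percentile = 25, sd_scale = 1.1) {
  if (target_test_frac < 0 || target_test_frac >= 1) {
    stop("`target_test_frac` must be in [0, 1)")
  }
  if (target_test_frac == 0) return(0)
  stopifnot_quant_matrix(X)
  pars <- threshold_params(X, percentile, sd_scale)
  x <- X$values[!is.na(X$values)]
  pr_censor <- if (pars$sd > 0) {
    stats::pnorm(x, mean = pars$mu, sd = pars$sd, lower.tail = FALSE)
  } else {
    as.numeric(x <= pars$mu)
  }
  max_frac <- mean(pr_censor)
  if (target_test_frac > max_frac) {
    stop(sprintf(
      "target test fraction %.3f unreachable; achievable range is [0, %.3f]",
      target_test_frac, max_frac))
  }
  target_test_frac / max_frac
}

#' MCAR partition: a uniformly random fraction of present entries held out
#'
#' Membership is independent of the entry's value, in contrast to
#' [mnar_partition()].
#'
#' @param X A [quant_matrix].
#' @param frac Fraction of present entries to hold out, in \[0, 1\].
#' @param seed Integer seed.
#' @param label Label given to held-out entries: `"test"` (default) or
#'   `"validation"`.
#' @return A `partition_mask`; non-held-out present entries are labelled
#'   train.
#' @export
mcar_partition <- function(X, frac, seed = 1L,
                           label = c("test", "validation")) {
  stopifnot_quant_matrix(X)
  label <- match.arg(label)
  if (frac < 0 || frac > 1) stop("`frac` must be in [0, 1]")
  code <- if (label == "test") 3L else 2L
  v <- X$values
  present <- which(!is.na(v))
  labels <- matrix(NA_integer_, nrow(v), ncol(v), dimnames = dimnames(v))
  with_seed(seed, {
    lab <- rep(1L, length(present))
    n_out <- round(frac * length(present))
    if (n_out > 0) lab[sample(length(present), n_out)] <- code
    labels[present] <- lab
  })
  new_partition_mask(labels, seed,
                     list(scheme = "mcar", frac = frac, label = label))
}

#' Biased (left-skewed) training batches
#'
#' Samples training batches with replacement, preferentially selecting
#' low-intensity entries: a candidate train entry with value `v` is accepted
#' outright when a fresh Gaussian threshold draw `t` satisfies `t >= v`, and
#' otherwise accepted with background probability `p_bg`; rejected candidates
#' are redrawn. The pooled batch-value distribution is therefore left-skewed
#' relative to the whole training set, concentrating gradient updates on the
#' low-abundance regime where MNAR missingness lives. Setting `p_bg = 1`
#' recovers unbiased uniform sampling with replacement. Test and validation
#' entries never appear in any batch.
#'
#' @param X A [quant_matrix].
#' @param mask A `partition_mask` for `X` with at least one train entry.
#' @param batch_size Entries per batch (default 128).
#' @param n_batches Number of batches to draw.
#' @param p_bg Background acceptance probability for above-threshold
#'   candidates (default 0.35).
#' @param percentile,sd_scale Thresholds-distribution parameters, shared with
#'   [make_thresholds()].
#' @param seed Integer seed.
#' @return A `batch_stream`: list with `batches` (list of integer vectors of
#'   linear entry indices into `X$values`) and `batch_size`.
#' @export
biased_batches <- function(X, mask, batch_size = 128, n_batches,
                           p_bg = 0.35, percentile = 25, sd_scale = 1.1,
                           seed = 1L) {
  stopifnot_quant_matrix(X)
  stopifnot_partition_mask(mask, X)
  train_idx <- mask_entries(mask, "train")
  if (length(train_idx) == 0) stop("mask has no train entries")
  vals <- X$values[train_idx]
  # the bias distribution is computed from the training entries only, so that
  # held-out values never influence batch selection
  pars <- if (length(vals) == 1) {
    list(mu = vals, sd = 0)
  } else {
    threshold_params_values(vals, percentile, sd_scale)
  }
  picks <- with_seed(seed, {
    cpp_biased_sample(vals, as.integer(batch_size) * as.integer(n_batches),
                      pars$mu, pars$sd, p_bg)
  })
  idx <- train_idx[picks]
  batches <- split(idx, rep(seq_len(n_batches), each = batch_size))
  names(batches) <- NULL
  structure(list(batches = batches, batch_size = as.integer(batch_size)),
            class = "batch_stream")
}

#' Write / read a partition mask as a three-column TSV
#'
#' Columns are `protein_id`, `sample_id`, `label`, one row per present entry,
#' enabling reproducible benchmarking across tools.
#'
#' @param mask A `partition_mask`.
#' @param X The [quant_matrix] the mask belongs to.
#' @param path File path.
#' @return `write_partition_mask` returns `path` invisibly;
#'   `read_partition_mask` returns a `partition_mask` aligned to `X`.
#' @export
write_partition_mask <- function(mask, X, path) {
  stopifnot_partition_mask(mask, X)
  idx <- which(!is.na(mask$labels))
  rc <- arrayInd(idx, dim(mask$labels))
  df <- data.frame(protein_id = rownames(X$values)[rc[, 1]],
                   sample_id = colnames(X$values)[rc[, 2]],
                   label = c("train", "validation", "test")[mask$labels[idx]])
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_partition_mask
#' @export
read_partition_mask <- function(path, X) {
  stopifnot_quant_matrix(X)
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  ri <- match(df$protein_id, rownames(X$values))
  ci <- match(df$sample_id, colnames(X$values))
  if (anyNA(ri) || anyNA(ci)) stop("mask refers to IDs absent from X")
  labels <- matrix(NA_integer_, nrow(X$values), ncol(X$values),
                   dimnames = dimnames(X$values))
  labels[cbind(ri, ci)] <- match(df$label, c("train", "validation", "test"))
  new_partition_mask(labels, NA_integer_, list(scheme = "file", path = path))
}
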