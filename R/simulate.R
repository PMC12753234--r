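#' Simulate a two-condition quantification study with spiked-in DA proteins
#'
#' Protein means are drawn from a Gaussian centred at `mean_center` (default
#' 12, a typical log-scale intensity) with standard deviation `mean_sd`;
#' per-protein standard deviations are drawn from a Gaussian centred at
#' `sd_center` with standard deviation `sd_sd` and redrawn until they exceed
#' `sd_floor`. Condition-1 rows are sampled from `N(m_i, s_i^2)`. A randomly
#' chosen `da_frac_each` of proteins then has its mean increased by
#' `delta_pct * m_i`, and a mutually exclusive `da_frac_each` decreased by the
#' same amount; condition-2 rows are sampled from these shifted means with the
#' same `s_i`. Proteins are i.i.d.; no plex structure, batch effects, or
#' between-protein correlation is simulated.
#'
#' @param n_proteins,n_samples Matrix shape per condition (defaults 10000 and
#'   128).
#' @param mean_center,mean_sd Gaussian parameters of the protein means
#'   (defaults 12 and 1).
#' @param sd_center,sd_sd Gaussian parameters of the protein standard
#'   deviations (defaults 1 and 1).
#' @param sd_floor Redraw threshold for sampled standard deviations (default
#'   0.05).
#' @param da_frac_each Fraction of proteins shifted up, and (disjointly) down
#'   (default 0.10 each).
#' @param delta_pct Mean shift of DA proteins as a fraction of the protein
#'   mean (e.g. 0.075 for a 7.5 percent shift).
#' @param seed Integer seed; the study is deterministic given the seed.
#' @return An object of class `simulated_study`: list with matrices `A` and
#'   `B` (proteins x samples, dimnames set), integer index sets `true_da_up`
#'   and `true_da_down`, vectors `protein_means` and `protein_sds`,
#'   `delta_pct`, and `seed`.
#' @export
simulate_da <- function(n_proteins = 10000, n_samples = 128,
                        mean_center = 12, mean_sd = 1.0,
                        sd_center = 1.0, sd_sd = 1.0, sd_floor = 0.05,
                        da_frac_each = 0.10, delta_pct, seed = 1L) {
  stopifnot(delta_pct >= 0)
  n_da <- round(da_frac_each * n_proteins)
  if (2 * n_da > n_proteins) stop("DA fractions infeasible")
  pids <- sprintf("prot%05d", seq_len(n_proteins))
  with_seed(seed, {
    m <- stats::rnorm(n_proteins, mean_center, mean_sd)
    s <- stats::rnorm(n_proteins, sd_center, sd_sd)
    while (any(s <= sd_floor)) {
      redo <- s <= sd_floor
      s[redo] <- stats::rnorm(sum(redo), sd_center, sd_sd)
    }
    da_idx <- sample(n_proteins, 2 * n_da)
    up <- sort(da_idx[seq_len(n_da)])
    down <- sort(da_idx[n_da + seq_len(n_da)])
    A <- matrix(stats::rnorm(n_proteins * n_samples), n_proteins) * s + m
    mB <- m
    mB[up] <- m[up] + m[up] * delta_pct
    mB[down] <- m[down] - m[down] * delta_pct
    B <- matrix(stats::rnorm(n_proteins * n_samples), n_proteins) * s + mB
    dimnames(A) <- list(pids, sprintf("A_%03d", seq_len(n_samples)))
    dimnames(B) <- list(pids, sprintf("B_%03d", seq_len(n_samples)))
    structure(list(A = A, B = B, true_da_up = up, true_da_down = down,
                   protein_means = m, protein_sds = s,
                   delta_pct = delta_pct, seed = seed),
              class = "simulated_study")
  })
}

#' @export
print.simulated_study <- function(x, ...) {
  cat(sprintf(
    "simulated_study: %d proteins x %d samples per condition, %d up / %d down DA (delta %.3g)\n",
    nrow(x$A), ncol(x$A), length(x$true_da_up), length(x$true_da_down),
    x$delta_pct))
  invisible(x)
}

#' Inject left-censored (MNAR) missingness, with MCAR top-up
#'
#' Entries are censored by the thresholds/Bernoulli machinery of
#' [mnar_partition()]: each entry falling below a Gaussian threshold draw is
#' removed with a Bernoulli probability calibrated analytically so that the
#' expected MNAR fraction matches `target_frac`. When the target exceeds the
#' maximum achievable MNAR fraction (the mean censoring probability at
#' Bernoulli probability 1), MNAR censoring saturates and the shortfall is
#' removed completely at random. Finally the missing count is trimmed or
#' topped up MCAR to hit `round(target_frac * n_entries)` exactly, so the
#' achieved fraction is within rounding of the target. Retained entries are
#' bit-identical to the input.
#'
#' @param M Numeric matrix (already-missing entries, if any, count towards the
#'   target).
#' @param target_frac Target overall missing fraction, in \[0, 1).
#' @param seed Integer seed.
#' @param percentile,sd_scale Thresholds-distribution parameters, as in
#'   [make_thresholds()].
#' @return The matrix with `NA` at censored entries.
#' @export
inject_missingness <- function(M, target_frac, seed = 1L,
                               percentile = 25, sd_scale = 1.1) {
  if (target_frac < 0 || target_frac >= 1) stop("`target_frac` must be in [0, 1)")
  if (target_frac == 0) return(M)
  n_entries <- length(M)
  n_target <- round(target_frac * n_entries)
  pres_idx <- which(!is.na(M))
  n_already <- n_entries - length(pres_idx)
  if (n_already >= n_target) return(M)
  x <- M[pres_idx]
  mu <- unname(stats::quantile(x, percentile / 100))
  sdev <- sd_scale * stats::sd(x)
  pr_censor <- if (sdev > 0) {
    stats::pnorm(x, mean = mu, sd = sdev, lower.tail = FALSE)
  } else {
    as.numeric(x <= mu)
  }
  need_frac <- (n_target - n_already) / length(pres_idx)
  max_frac <- mean(pr_censor)
  p <- min(1, need_frac / max_frac)
  with_seed(seed, {
    thr <- stats::rnorm(length(x), mean = mu, sd = sdev)
    drop <- (thr >= x) & (stats::runif(length(x)) < p)
    n_miss <- n_already + sum(drop)
    if (n_miss < n_target) {
      # MCAR top-up among surviving entries
      surv <- which(!drop)
      extra <- sample(surv, n_target - n_miss)
      drop[extra] <- TRUE
    } else if (n_miss > n_target) {
      # trim the overshoot at random among censored entries
      rm_idx <- which(drop)
      keep_back <- sample(rm_idx, n_miss - n_target)
      drop[keep_back] <- FALSE
    }
    M[pres_idx[drop]] <- NA_real_
  })
  M
}

#' End-to-end DA recovery experiment on simulated data
#'
#' Runs the full pipeline behind the simulation benchmark: simulate two
#' conditions with spiked-in DA proteins, optionally inject MNAR missingness
#' into the concatenated matrix, optionally impute, run paired t-tests between
#' matched columns of the two conditions, and score the p-value ranking
#' against the known DA labels with precision-recall AUC.
#'
#' @param n_proteins,n_samples Study shape per condition.
#' @param delta_pct DA mean shift as a fraction of the protein mean.
#' @param missing_frac Overall missingness injected before analysis (0 for
#'   none).
#' @param impute One of `"none"` (t-tests drop incomplete pairs per protein),
#'   `"lupine"` (ensemble imputation), `"gaussian"` (down-shift baseline), or
#'   `"knn"`.
#' @param n_models,grid Ensemble settings for `impute = "lupine"`.
#' @param seed Integer seed driving the generator, the missingness, and the
#'   imputation.
#' @param ... Passed to [ensemble_impute()] (e.g. `max_epochs`).
#' @return List with `pr_auc`, the per-protein `tests` data frame, the `truth`
#'   binary vector, the `sim` study, and the analysed matrix `M`.
#' @export
run_da_simulation <- function(n_proteins = 10000, n_samples = 128,
                              delta_pct = 0.075, missing_frac = 0,
                              impute = c("none", "lupine", "gaussian", "knn"),
                              n_models = 3, grid = reduced_grid(),
                              seed = 1L, ...) {
  impute <- match.arg(impute)
  sim <- simulate_da(n_proteins = n_proteins, n_samples = n_samples,
                     delta_pct = delta_pct, seed = seed)
  joint <- cbind(sim$A, sim$B)
  if (missing_frac > 0) {
    joint <- inject_missingness(joint, missing_frac, seed = seed + 1L)
  }
  M <- switch(impute,
    none = joint,
    lupine = {
      qm <- quant_matrix(joint)
      res <- ensemble_impute(qm, n_models = n_models, grid = grid,
                             base_seed = seed + 2L, ...)
      res$imputed$values
    },
    gaussian = gaussian_downshift_impute(quant_matrix(joint), seed = seed + 2L),
    knn = knn_impute(quant_matrix(joint))
  )
  pairs <- cbind(seq_len(n_samples), n_samples + seq_len(n_samples))
  tests <- paired_t_tests(M, pairs)
  truth <- integer(n_proteins)
  truth[c(sim$true_da_up, sim$true_da_down)] <- 1L
  auc <- pr_auc(tests$p_value, truth, tiebreak = abs(tests$log2_fc))
  list(pr_auc = auc, tests = tests, truth = truth, sim = sim, M = M)
}
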