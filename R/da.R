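#' Proteins eligible for differential-abundance analysis
#'
#' Proteins whose pre-imputation missingness exceeds `max_frac` are excluded
#' from DA analysis (a protein missing in exactly half of the samples is
#' kept; the cutoff is a strict greater-than).
#'
#' @param X_preimpute A [quant_matrix] of the matrix *before* imputation.
#' @param max_frac Maximum tolerated missing fraction (default 0.5).
#' @return Integer vector of kept protein row indices, named by protein ID.
#' @export
exclude_high_missingness <- function(X_preimpute, max_frac = 0.5) {
  stopifnot_quant_matrix(X_preimpute)
  v <- X_preimpute$values
  frac <- rowMeans(is.na(v))
  keep <- which(frac <= max_frac)
  names(keep) <- rownames(v)[keep]
  keep
}

#' Paired t-tests between matched sample columns
#'
#' For every protein (row), computes the classical paired t-test on the
#' per-pair differences `M[, pairs[, 2]] - M[, pairs[, 1]]`. The log2 fold
#' change is the mean difference — the input is assumed to already be on a
#' log2 scale, so no re-logging is applied. Pairs with either member missing
#' are dropped per protein; a protein with fewer than two usable pairs, or
#' zero variance of the differences, is flagged excluded (`t` and `p` are
#' `NA`) rather than aborting the analysis.
#'
#' @param M Numeric matrix (proteins x samples), possibly with `NA`.
#' @param pairs Two-column integer matrix of column indices: column 1 the
#'   reference condition, column 2 the condition of interest.
#' @return Data frame with one row per protein: `protein`, `t`, `p_value`,
#'   `log2_fc`, `n_pairs`, `excluded`.
#' @export
paired_t_tests <- function(M, pairs) {
  pairs <- as.matrix(pairs)
  if (ncol(pairs) != 2) stop("`pairs` must have two columns")
  D <- M[, pairs[, 2], drop = FALSE] - M[, pairs[, 1], drop = FALSE]
  n <- rowSums(!is.na(D))
  mean_d <- rowMeans(D, na.rm = TRUE)
  ss <- rowSums(D^2, na.rm = TRUE) - n * mean_d^2
  var_d <- ifelse(n > 1, pmax(ss, 0) / (n - 1), NA_real_)
  tstat <- ifelse(n >= 2 & var_d > 0,
                  mean_d / sqrt(var_d / n), NA_real_)
  p <- 2 * stats::pt(-abs(tstat), df = n - 1)
  excluded <- n < 2 | is.na(var_d) | var_d == 0
  tstat[excluded] <- NA_real_
  p[excluded] <- NA_real_
  data.frame(protein = rownames(M) %||% as.character(seq_len(nrow(M))),
             t = tstat, p_value = p,
             log2_fc = ifelse(n >= 1, mean_d, NA_real_),
             n_pairs = n, excluded = excluded,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment with monotonicity enforcement,
#' capped at 1. `NA` p-values (excluded proteins) stay `NA` and do not count
#' towards the number of tests.
#'
#' @param p_values Numeric vector of p-values in \[0, 1\] (NA allowed).
#' @return Vector of adjusted p-values, same length and order.
#' @export
bh_adjust <- function(p_values) {
  ok <- !is.na(p_values)
  if (any(p_values[ok] < 0 | p_values[ok] > 1)) {
    stop("p-values must lie in [0, 1]")
  }
  adj <- rep(NA_real_, length(p_values))
  adj[ok] <- stats::p.adjust(p_values[ok], method = "BH")
  adj
}

#' Call differentially abundant proteins
#'
#' A protein is called up-regulated when its BH-adjusted p-value is below
#' `alpha` and its log2 fold change exceeds `lfc` (strict inequalities; a fold
#' change of exactly `lfc` is not called), down-regulated for `adj_p < alpha`
#' and `log2_fc < -lfc`, excluded when the test was excluded, and otherwise
#' not DA.
#'
#' @param stats Data frame from [paired_t_tests()] (columns `p_value`,
#'   `log2_fc`, `excluded`).
#' @param alpha Adjusted-p cutoff (default 0.01).
#' @param lfc Absolute log2 fold-change cutoff (default 0.5).
#' @return The input data frame with columns `adj_p` and `call` (factor with
#'   levels up, down, not_da, excluded) appended.
#' @export
call_da <- function(stats, alpha = 0.01, lfc = 0.5) {
  adj_p <- bh_adjust(stats$p_value)
  call <- rep("not_da", nrow(stats))
  call[!is.na(adj_p) & adj_p < alpha & stats$log2_fc > lfc] <- "up"
  call[!is.na(adj_p) & adj_p < alpha & stats$log2_fc < -lfc] <- "down"
  call[stats$excluded] <- "excluded"
  stats$adj_p <- adj_p
  stats$call <- factor(call, levels = c("up", "down", "not_da", "excluded"))
  stats
}

#' Precision-recall AUC (average precision) of a p-value ranking
#'
#' Proteins are ranked by ascending p-value, ties broken by descending
#' `tiebreak` (typically the absolute log2 fold change) when supplied and by
#' stable order otherwise; `NA` p-values rank last. The area is the
#' non-interpolated average precision: the mean, over true positives, of the
#' precision at each positive's rank. A random ranking scores about the
#' prevalence of positives; a perfect ranking scores 1.
#'
#' @param p_values Numeric vector of p-values (NA allowed, ranked last).
#' @param truth Binary vector (0/1 or logical) of the same length with at
#'   least one positive.
#' @param tiebreak Optional numeric tie-breaker, larger is earlier.
#' @return The average precision, a single number in (0, 1\].
#' @export
pr_auc <- function(p_values, truth, tiebreak = NULL) {
  truth <- as.integer(as.logical(truth))
  if (length(truth) != length(p_values)) stop("length mismatch")
  n_pos <- sum(truth)
  if (n_pos == 0) stop("`truth` contains no positives")
  key <- p_values
  key[is.na(key)] <- Inf
  ord <- if (is.null(tiebreak)) {
    order(key)
  } else {
    order(key, -tiebreak)
  }
  y <- truth[ord]
  precision_at <- cumsum(y) / seq_along(y)
  sum(precision_at * y) / n_pos
}

#' Within-complex versus random protein-pair correlations
#'
#' For each annotated protein complex with at least two usable subunits,
#' computes the Spearman correlation over samples for every within-complex
#' protein pair, then draws an equal number of random protein pairs (distinct
#' proteins, excluding any pair that co-occurs in a complex) from the usable
#' proteins. Proteins whose pre-imputation missingness exceeds `max_missing`
#' are removed first. The matched lists are compared with a paired t-test.
#'
#' @param X A [quant_matrix], typically imputed (dense).
#' @param membership Data frame with columns `complex_id` and `protein_id`.
#' @param max_missing Pre-imputation missingness cutoff (default 0.5).
#' @param preimpute Optional [quant_matrix] giving pre-imputation missingness;
#'   defaults to `X` itself.
#' @param seed Integer seed for the random pairs.
#' @return An object of class `complex_corr_report`: list with
#'   `within_correlations`, `random_correlations` (equal length),
#'   `mean_within`, `mean_random`, `paired_test_p`, and `n_complexes`.
#' @export
complex_correlations <- function(X, membership, max_missing = 0.5,
                                 preimpute = NULL, seed = 1L) {
  stopifnot_quant_matrix(X)
  if (!all(c("complex_id", "protein_id") %in% names(membership))) {
    stop("`membership` needs columns complex_id and protein_id")
  }
  keep <- names(exclude_high_missingness(preimpute %||% X, max_missing))
  v <- X$values[rownames(X$values) %in% keep, , drop = FALSE]
  membership <- membership[membership$protein_id %in% rownames(v), ]
  complexes <- split(unique(membership[c("complex_id", "protein_id")])$protein_id,
                     unique(membership[c("complex_id", "protein_id")])$complex_id)
  complexes <- Filter(function(p) length(p) >= 2, complexes)
  if (length(complexes) == 0) {
    stop("no complex has at least two usable proteins in X")
  }
  within_pairs <- do.call(rbind, lapply(complexes, function(p) {
    t(utils::combn(sort(p), 2))
  }))
  pair_key <- function(a, b) paste(pmin(a, b), pmax(a, b), sep = "\r")
  within_keys <- unique(pair_key(within_pairs[, 1], within_pairs[, 2]))
  rho_of <- function(a, b) {
    stats::cor(v[a, ], v[b, ], method = "spearman",
               use = "pairwise.complete.obs")
  }
  within <- mapply(rho_of, within_pairs[, 1], within_pairs[, 2],
                   USE.NAMES = FALSE)
  universe <- rownames(v)
  if (length(universe) < 2) stop("fewer than two usable proteins")
  n_needed <- length(within)
  random <- numeric(n_needed)
  with_seed(seed, {
    for (k in seq_len(n_needed)) {
      repeat {
        pr <- sample(universe, 2)
        if (!(pair_key(pr[1], pr[2]) %in% within_keys)) break
      }
      random[k] <- rho_of(pr[1], pr[2])
    }
  })
  pt <- if (n_needed >= 2) stats::t.test(within, random, paired = TRUE)$p.value
        else NA_real_
  structure(list(within_correlations = unname(within),
                 random_correlations = random,
                 mean_within = mean(within, na.rm = TRUE),
                 mean_random = mean(random, na.rm = TRUE),
                 paired_test_p = pt,
                 n_complexes = length(complexes)),
            class = "complex_corr_report")
}

#' @export
print.complex_corr_report <- function(x, ...) {
  cat(sprintf(
    "complex_corr_report: %d complexes, %d pairs; mean rho within %.3f vs random %.3f (paired p = %.3g)\n",
    x$n_complexes, length(x$within_correlations),
    x$mean_within, x$mean_random, x$paired_test_p))
  invisible(x)
}
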