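# Independent brute-force oracles, deliberately written as plain loops so they
# share no code with the implementation they check.

# Step-up BH from the definition: sort, multiply by n/rank, enforce
# monotonicity from the largest p downwards, cap at 1.
bh_brute_force <- function(p) {
  n <- length(p)
  ord <- order(p)
  adj <- numeric(n)
  prev <- 1
  for (k in n:1) {
    val <- min(prev, p[ord[k]] * n / k)
    adj[ord[k]] <- val
    prev <- val
  }
  pmin(adj, 1)
}

# Exact one-sided rank-sum p-value by enumeration of all C(10, 5) splits:
# probability, under exchangeability, that the rank sum of the first group is
# <= the observed rank sum (alternative: group 1 stochastically smaller).
ranksum_exact_p <- function(x, y) {
  pooled <- c(x, y)
  r <- rank(pooled)
  obs <- sum(r[seq_along(x)])
  combos <- utils::combn(length(pooled), length(x))
  sums <- apply(combos, 2, function(idx) sum(r[idx]))
  mean(sums <= obs)
}

# Full reimplementation of the stopping rule with explicit loops.
convergence_oracle <- function(trace, tol = 0.001, patience = 10) {
  n <- length(trace)
  if (n >= patience + 1) {
    n_ok <- 0
    best <- Inf
    ok <- logical(n)
    for (k in seq_len(n)) {
      if (!is.finite(best)) {
        ok[k] <- FALSE
      } else if (best <= 0) {
        ok[k] <- TRUE
      } else {
        ok[k] <- (best - trace[k]) / best < tol
      }
      best <- min(best, trace[k])
    }
    if (all(ok[(n - patience + 1):n])) {
      return(list(stop = TRUE, reason = "tolerance"))
    }
  }
  if (n >= 15) {
    w2 <- trace[(n - 14):(n - 10)]
    w1 <- trace[(n - 4):n]
    if (ranksum_exact_p(w2, w1) < 0.05) {
      return(list(stop = TRUE, reason = "wilcoxon"))
    }
  }
  list(stop = FALSE, reason = "none")
}

# Average precision from its definition, one rank at a time.
ap_brute_force <- function(p, truth) {
  ord <- order(p)
  y <- truth[ord]
  tp <- 0
  total <- 0
  for (k in seq_along(y)) {
    if (y[k] == 1) {
      tp <- tp + 1
      total <- total + tp / k
    }
  }
  total / sum(truth)
}
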