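test_that("high-missingness exclusion uses a strict 50% cutoff", {
  v <- matrix(NA_real_, 3, 100,
              dimnames = list(c("half", "full", "over"), sprintf("S%03d", 1:100)))
  v["half", 1:50] <- 1
  v["full", ] <- 1
  v["over", 1:49] <- 1 # 51 missing
  keep <- exclude_high_missingness(quant_matrix(v))
  expect_setequal(names(keep), c("half", "full"))
})

test_that("paired t-tests match the closed form and stats::t.test", {
  # three pairs with differences 1, 2, 3: t = 2 / (1 / sqrt(3))
  M <- rbind(p1 = c(0, 0, 0, 1, 2, 3))
  res <- paired_t_tests(M, cbind(1:3, 4:6))
  expect_equal(res$t, 2 * sqrt(3), tolerance = 1e-12)
  expect_equal(res$t, 3.4641, tolerance = 1e-4)
  expect_equal(res$log2_fc, 2)

  # agreement with t.test on random data with missing values
  set.seed(9)
  M2 <- matrix(rnorm(200), 10)
  M2[sample(200, 30)] <- NA
  rownames(M2) <- sprintf("P%02d", 1:10)
  pairs <- cbind(1:10, 11:20)
  res2 <- paired_t_tests(M2, pairs)
  for (i in 1:10) {
    d <- M2[i, 11:20] - M2[i, 1:10]
    d <- d[!is.na(d)]
    if (length(d) >= 2 && sd(d) > 0) {
      tt <- t.test(d)
      expect_equal(res2$t[i], unname(tt$statistic), tolerance = 1e-10)
      expect_equal(res2$p_value[i], tt$p.value, tolerance = 1e-10)
    } else {
      expect_true(res2$excluded[i])
    }
  }

  # shift invariance
  res3 <- paired_t_tests(M2 + 5, pairs)
  expect_equal(res3$t, res2$t)
  expect_equal(res3$log2_fc, res2$log2_fc)

  # identical columns give zero-variance differences -> excluded
  same <- rbind(p = c(1, 2, 3, 1, 2, 3))
  expect_true(paired_t_tests(same, cbind(1:3, 4:6))$excluded)
})

test_that("BH adjustment equals brute force on 1000 random vectors", {
  set.seed(10)
  worst <- 0
  for (k in 1:1000) {
    p <- runif(sample(1:50, 1))
    worst <- max(worst, max(abs(bh_adjust(p) - bh_brute_force(p))))
  }
  expect_lt(worst, 1e-12)
  expect_equal(bh_adjust(0.03), 0.03)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(rep(1, 5)), rep(1, 5))
  expect_error(bh_adjust(c(0.5, 1.2)), "0, 1")
  # monotone: adjusted never below raw
  set.seed(11)
  p <- runif(100)
  expect_true(all(bh_adjust(p) >= p))
})

test_that("DA calls respect strict thresholds and are monotone in alpha", {
  stats <- data.frame(protein = c("a", "b", "c", "d"),
                      t = c(5, 5, 2, NA),
                      p_value = c(1e-5, 1e-5, 0.5, NA),
                      log2_fc = c(0.6, 0.5, 3, 1),
                      excluded = c(FALSE, FALSE, FALSE, TRUE))
  res <- call_da(stats)
  expect_equal(as.character(res$call), c("up", "not_da", "not_da", "excluded"))
  # down call
  stats$log2_fc[1] <- -0.6
  expect_equal(as.character(call_da(stats)$call[1]), "down")

  set.seed(12)
  big <- data.frame(protein = sprintf("P%03d", 1:200),
                    t = rnorm(200),
                    p_value = runif(200)^2,
                    log2_fc = rnorm(200),
                    excluded = FALSE)
  n_calls <- sapply(c(0.001, 0.01, 0.05, 0.2),
                    function(a) sum(call_da(big, alpha = a)$call %in% c("up", "down")))
  expect_true(all(diff(n_calls) >= 0))
})

test_that("average precision matches hand cases, brute force, and the prevalence baseline", {
  # ranks P, N, P, N -> (1/1 + 2/3) / 2
  expect_equal(pr_auc(c(0.01, 0.02, 0.03, 0.04), c(1, 0, 1, 0)),
               (1 + 2 / 3) / 2)
  expect_equal(pr_auc(c(0.01, 0.02), c(1, 1)), 1.0)
  # random ranking scores about the prevalence
  set.seed(13)
  truth <- as.integer(runif(10000) < 0.2)
  auc <- pr_auc(runif(10000), truth)
  expect_lt(abs(auc - 0.2), 0.02)
  # invariance to strictly monotone transforms of the p-values
  p <- runif(500)
  y <- as.integer(runif(500) < 0.3)
  expect_equal(pr_auc(p, y), pr_auc(qnorm(p), y))
  expect_equal(pr_auc(p, y), pr_auc(p^3, y))
  # agreement with the loop oracle
  expect_equal(pr_auc(p, y), ap_brute_force(p, y))
  expect_error(pr_auc(p, rep(0, 500)), "positives")
})

test_that("a null pipeline controls the DA call rate", {
  for (s in 1:5) {
    r <- run_da_simulation(n_proteins = 1000, n_samples = 32, delta_pct = 0,
                           missing_frac = 0, impute = "none", seed = s)
    called <- call_da(r$tests)
    expect_lte(sum(called$call %in% c("up", "down")), 10)
  }
})

test_that("complex correlations separate correlated complexes from random pairs", {
  # complex of 3 proteins following a shared latent signal, plus noise proteins
  set.seed(14)
  m <- 40
  latent <- rnorm(m)
  v <- rbind(cx1 = latent + rnorm(m, 0, 0.1),
             cx2 = latent + rnorm(m, 0, 0.1),
             cx3 = latent + rnorm(m, 0, 0.1),
             matrix(rnorm(20 * m), 20,
                    dimnames = list(sprintf("bg%02d", 1:20), NULL)))
  colnames(v) <- sprintf("S%02d", 1:m)
  qm <- quant_matrix(v)
  membership <- data.frame(complex_id = "C1",
                           protein_id = c("cx1", "cx2", "cx3"))
  rep1 <- complex_correlations(qm, membership, seed = 15)
  # C(3, 2) within pairs, matched count of random pairs
  expect_equal(length(rep1$within_correlations), 3L)
  expect_equal(length(rep1$random_correlations), 3L)
  expect_gt(rep1$mean_within, 0.9)
  expect_gt(rep1$mean_within, rep1$mean_random)

  # two perfectly correlated subunits give rho exactly 1
  v2 <- rbind(a = 1:10, b = (1:10) * 2 + 3,
              matrix(rnorm(50), 5, dimnames = list(paste0("n", 1:5), NULL)))
  colnames(v2) <- paste0("S", 1:10)
  rep2 <- complex_correlations(quant_matrix(v2),
                               data.frame(complex_id = "C", protein_id = c("a", "b")),
                               seed = 16)
  expect_equal(rep2$within_correlations, 1.0)
})

test_that("random-pair correlations on i.i.d. noise centre on zero", {
  set.seed(17)
  v <- matrix(rnorm(200 * 30), 200,
              dimnames = list(sprintf("P%03d", 1:200), sprintf("S%02d", 1:30)))
  qm <- quant_matrix(v)
  # one big complex yields C(46, 2) = 1035 matched random pairs
  membership <- data.frame(complex_id = "C1",
                           protein_id = sprintf("P%03d", 1:46))
  rep <- complex_correlations(qm, membership, seed = 18)
  expect_equal(length(rep$random_correlations), choose(46, 2))
  expect_lt(abs(mean(rep$random_correlations)), 0.05)
})
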