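test_that("initialization is deterministic, correctly shaped, and bounded", {
  hp <- hyperparams(2, 2, 1, 4)
  s1 <- init_model(10, 6, hp, seed = 42)
  s2 <- init_model(10, 6, hp, seed = 42)
  expect_identical(s1, s2)
  expect_equal(dim(s1$W), c(10L, 2L))
  expect_equal(dim(s1$H), c(2L, 6L))
  expect_equal(dim(s1$mlp[[1]]$weight), c(4L, 4L))
  expect_equal(length(s1$mlp[[1]]$bias), 4L)
  expect_equal(dim(s1$mlp[[2]]$weight), c(1L, 4L))
  expect_equal(length(s1$mlp[[2]]$bias), 1L)

  hp16 <- hyperparams(16, 4, 1, 8)
  s <- init_model(500, 50, hp16, seed = 1)
  expect_true(all(abs(s$W) <= 1 / sqrt(16)))
  expect_true(all(abs(s$H) <= 1 / sqrt(4)))
  expect_true(all(abs(s$mlp[[1]]$weight) <= 1 / sqrt(20)))
})

test_that("forward pass matches hand-computed values and the leaky slope", {
  hp <- hyperparams(1, 1, 1, 2)
  state <- init_model(1, 1, hp, seed = 1)
  # hand-set parameters: input (w, h) = (0.3, 0.7)
  state$W[1, 1] <- 0.3
  state$H[1, 1] <- 0.7
  state$mlp[[1]]$weight <- matrix(c(1, -1, 2, 1), 2, 2) # rows: hidden units
  state$mlp[[1]]$bias <- c(0.5, -0.5)
  state$mlp[[2]]$weight <- matrix(c(2, 3), 1, 2)
  state$mlp[[2]]$bias <- 0.25
  # z1 = 1*0.3 + 2*0.7 + 0.5 = 2.2 (positive, unchanged)
  # z2 = -1*0.3 + 1*0.7 - 0.5 = -0.1 -> leaky 0.1 * -0.1 = -0.01
  # out = 2*2.2 + 3*(-0.01) + 0.25 = 4.62
  expect_equal(forward(state, 1, 1), 4.62)

  # negative slope exactly 0.1: single hidden unit forced to pre-activation -1
  hp1 <- hyperparams(1, 1, 1, 1)
  st <- init_model(1, 1, hp1, seed = 1)
  st$W[1, 1] <- -1
  st$H[1, 1] <- 0
  st$mlp[[1]]$weight <- matrix(c(1, 0), 1, 2)
  st$mlp[[1]]$bias <- 0
  st$mlp[[2]]$weight <- matrix(1, 1, 1)
  st$mlp[[2]]$bias <- 0
  expect_equal(forward(st, 1, 1), -0.1)

  # all-zero parameters predict zero everywhere
  z <- init_model(3, 3, hp, seed = 2)
  z$W[] <- 0; z$H[] <- 0
  for (l in seq_along(z$mlp)) {
    z$mlp[[l]]$weight[] <- 0
    z$mlp[[l]]$bias[] <- 0
  }
  expect_equal(forward(z, 1:3, c(1, 2, 3)), c(0, 0, 0))
  expect_true(all(predict_all(z) == 0))
  expect_error(forward(z, 4, 1), "out of range")
})

test_that("compiled dense prediction agrees with the R forward pass", {
  hp <- hyperparams(5, 3, 2, 7)
  state <- init_model(12, 9, hp, seed = 3)
  pred <- predict_all(state)
  expect_false(anyNA(pred))
  ij <- expand.grid(i = 1:12, j = 1:9)
  expect_equal(pred[cbind(ij$i, ij$j)], forward(state, ij$i, ij$j),
               tolerance = 1e-12)
})

test_that("stopping rule handles plateaus, steady improvement, and rising error", {
  # strictly halving losses never stop
  halving <- 2^-(1:40)
  expect_false(convergence_check(halving)$stop)
  # constant losses plateau out via the tolerance criterion
  flat <- rep(1, 11)
  res <- convergence_check(flat)
  expect_true(res$stop)
  expect_equal(res$reason, "tolerance")
  # short traces never stop
  expect_false(convergence_check(c(1, 0.5))$stop)
  # error that bottomed out and rose again: the older window (epochs n-14 ..
  # n-10) is uniformly below the recent window, so the one-sided rank-sum
  # test reaches its extreme 5-vs-5 p-value of 1/252 < 0.05; a fresh best at
  # epoch n-5 keeps the tolerance plateau from accumulating first
  rising <- c(2, 1.9, 1.8,
              0.40, 0.39, 0.38, 0.37, 0.36,
              0.9, 0.95, 1.0, 1.05, 0.35,
              0.9, 0.95, 1.0, 1.05, 1.1)
  res2 <- convergence_check(rising)
  expect_true(res2$stop)
  expect_equal(res2$reason, "wilcoxon")
  expect_lt(ranksum_exact_p(rising[4:8], rising[14:18]), 0.05)
})

test_that("stopping rule agrees with the exact-enumeration oracle on 1000 random traces", {
  set.seed(77)
  mismatches <- 0L
  for (k in 1:1000) {
    n <- sample(1:30, 1)
    trace <- cumprod(runif(n, 0.7, 1.3)) # multiplicative random walk
    a <- convergence_check(trace)
    b <- convergence_oracle(trace)
    if (!identical(a$stop, b$stop) || !identical(a$reason, b$reason)) {
      mismatches <- mismatches + 1L
    }
  }
  expect_equal(mismatches, 0L)
})

test_that("training recovers additive structure on a noisy rank-1 matrix", {
  qm <- rank1_qm(100, 20, noise_sd = 0.1, seed = 5)
  mask <- mcar_partition(qm, 0.2, seed = 6, label = "validation")
  fit <- train_model(qm, mask, tiny_hp(max_epochs = 150), seed = 7)
  final <- tail(fit$trace$val_mse_by_epoch, 1)
  expect_lt(final, 0.1)
  expect_lt(min(fit$trace$val_mse_by_epoch),
            fit$trace$val_mse_by_epoch[1] / 5)
  expect_equal(fit$trace$epochs_run, length(fit$trace$val_mse_by_epoch))

  # reconstruction correlates with the ground truth on held-out entries
  pred <- predict_all(fit$state)
  held <- mask_entries(mask, "validation")
  expect_gt(cor(pred[held], qm$values[held]), 0.9)
})

test_that("training is deterministic and respects the epoch cap", {
  qm <- rank1_qm(40, 10, seed = 8)
  mask <- mcar_partition(qm, 0.2, seed = 1, label = "validation")
  f1 <- train_model(qm, mask, tiny_hp(max_epochs = 5), seed = 9)
  f2 <- train_model(qm, mask, tiny_hp(max_epochs = 5), seed = 9)
  expect_identical(f1$trace$val_mse_by_epoch, f2$trace$val_mse_by_epoch)
  expect_identical(f1$state$W, f2$state$W)
  expect_identical(f1$state$mlp, f2$state$mlp)

  one <- train_model(qm, mask, tiny_hp(max_epochs = 1), seed = 9)
  expect_equal(one$trace$epochs_run, 1L)
  expect_equal(one$trace$stop_reason, "max_epochs")
})

test_that("validation entries never contribute gradient", {
  qm <- rank1_qm(40, 10, seed = 10)
  mask <- mcar_partition(qm, 0.2, seed = 2, label = "validation")
  hp <- tiny_hp(max_epochs = 3) # fixed epochs so stopping cannot differ
  f1 <- train_model(qm, mask, hp, seed = 11)
  v2 <- qm$values
  v2[mask_entries(mask, "validation")] <- v2[mask_entries(mask, "validation")] + 100
  f2 <- train_model(quant_matrix(v2, qm$dataset), mask, hp, seed = 11)
  expect_identical(f1$state$W, f2$state$W)
  expect_identical(f1$state$H, f2$state$H)
  expect_identical(f1$state$mlp, f2$state$mlp)
  # only the reported validation MSE differs
  expect_false(identical(f1$trace$val_mse_by_epoch, f2$trace$val_mse_by_epoch))
})

test_that("training requires a validation split and checkpoints round-trip", {
  qm <- rank1_qm(20, 8, seed = 12)
  mask <- mcar_partition(qm, 0, seed = 1) # all train, no validation
  expect_error(train_model(qm, mask, tiny_hp(), seed = 1), "validation")

  mask2 <- mcar_partition(qm, 0.2, seed = 3, label = "validation")
  fit <- train_model(qm, mask2, tiny_hp(max_epochs = 2), seed = 4)
  f <- withr::local_tempfile(fileext = ".rds")
  save_model(fit$state, f)
  expect_identical(load_model(f), fit$state)
})
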