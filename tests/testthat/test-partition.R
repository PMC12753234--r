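test_that("thresholds matrix has the requested Gaussian moments", {
  qm <- random_qm(500, 200, miss_frac = 0.1, seed = 2)
  thr <- make_thresholds(qm, seed = 11)
  expect_equal(dim(thr), dim(qm$values))
  expect_false(anyNA(thr))
  pres <- qm$values[!is.na(qm$values)]
  q25 <- unname(quantile(pres, 0.25))
  target_sd <- 1.1 * sd(pres)
  se <- target_sd / sqrt(length(thr))
  expect_lt(abs(mean(thr) - q25), 3 * se)
  expect_lt(abs(sd(thr) / target_sd - 1), 0.02)

  # degenerate sd: constant matrix gives a constant thresholds matrix
  cst <- quant_matrix(matrix(7, 4, 5, dimnames = list(paste0("P", 1:4),
                                                      paste0("S", 1:5))))
  expect_true(all(make_thresholds(cst, seed = 1) == 7))

  # percentile 50 on symmetric values centres T on the median
  sym <- random_qm(300, 100, miss_frac = 0, seed = 3)
  thr50 <- make_thresholds(sym, percentile = 50, seed = 4)
  expect_lt(abs(mean(thr50) - median(sym$values)), 0.02)
})

test_that("MNAR partition labels every present entry once and is reproducible", {
  qm <- random_qm(50, 20, miss_frac = 0.25, seed = 7)
  mask <- mnar_partition(qm, val_frac = 0.1, seed = 3)
  pres <- !is.na(qm$values)
  expect_true(all(!is.na(mask$labels[pres])))
  expect_true(all(is.na(mask$labels[!pres])))
  expect_true(all(mask$labels[pres] %in% 1:3))
  expect_identical(mask$labels, mnar_partition(qm, val_frac = 0.1, seed = 3)$labels)
  expect_false(identical(mask$labels, mnar_partition(qm, val_frac = 0.1, seed = 4)$labels))
})

test_that("MNAR partition with Bernoulli p = 0 sends everything to train", {
  qm <- random_qm(30, 10, miss_frac = 0, seed = 1)
  m0 <- mnar_partition(qm, bernoulli_p = 0, seed = 5)
  expect_equal(sum(m0$labels == 3L, na.rm = TRUE), 0L)
  expect_equal(sum(m0$labels == 1L, na.rm = TRUE), length(qm$values))
})

test_that("MNAR test sets are left-shifted and hit the calibrated 20% fraction", {
  qm <- random_qm(200, 50, miss_frac = 0, seed = 909)
  fracs <- sapply(1:10, function(s) {
    mask <- mnar_partition(qm, seed = s)
    te <- qm$values[mask$labels == 3L]
    tr <- qm$values[mask$labels == 1L]
    expect_lt(mean(te), mean(tr))
    length(te) / sum(!is.na(qm$values))
  })
  # 0.61 was tuned for a 20% test fraction; standard-normal X lands close
  expect_lt(abs(mean(fracs) - 0.20), 0.03)
})

test_that("Bernoulli calibration reproduces the target fraction and flags unreachable targets", {
  qm <- random_qm(200, 50, miss_frac = 0, seed = 10)
  p <- calibrate_bernoulli_p(qm, 0.2)
  fracs <- sapply(1:20, function(s) {
    mask <- mnar_partition(qm, bernoulli_p = p, seed = s)
    sum(mask$labels == 3L, na.rm = TRUE) / length(qm$values)
  })
  expect_lt(abs(mean(fracs) - 0.20), 0.01)
  expect_equal(calibrate_bernoulli_p(qm, 0), 0)
  # a constant matrix censors with probability exactly 1 (T == c >= c)
  cst <- quant_matrix(matrix(3, 5, 10, dimnames = list(paste0("P", 1:5),
                                                       paste0("S", 1:10))))
  expect_equal(calibrate_bernoulli_p(cst, 0.33), 0.33)
  expect_error(calibrate_bernoulli_p(qm, 0.9), "achievable range")
})

test_that("MCAR partition has binomial-sized, value-independent test sets", {
  qm <- random_qm(100, 100, miss_frac = 0, seed = 12)
  mask <- mcar_partition(qm, 0.1, seed = 1)
  n_test <- sum(mask$labels == 3L)
  expect_lt(abs(n_test - 1000), 4 * sqrt(10000 * 0.1 * 0.9))
  expect_equal(sum(mcar_partition(qm, 0)$labels == 3L, na.rm = TRUE), 0L)
  expect_equal(sum(mcar_partition(qm, 1)$labels == 3L, na.rm = TRUE), 10000L)
  # correlation between value and test membership vanishes on average
  cors <- sapply(1:30, function(s) {
    m <- mcar_partition(qm, 0.2, seed = s)
    cor(as.numeric(qm$values), as.numeric(m$labels == 3L))
  })
  expect_lt(abs(mean(cors)), 0.02)
  # validation labelling variant
  mv <- mcar_partition(qm, 0.1, seed = 2, label = "validation")
  expect_gt(sum(mv$labels == 2L), 0)
  expect_equal(sum(mv$labels == 3L), 0L)
})

test_that("biased batches are left-skewed, train-only, and unbiased at p_bg = 1", {
  qm <- random_qm(100, 40, miss_frac = 0, seed = 20)
  mask <- mnar_partition(qm, seed = 2)
  train_vals <- qm$values[mask_entries(mask, "train")]
  bs <- biased_batches(qm, mask, batch_size = 128, n_batches = 100, seed = 3)
  expect_equal(length(bs$batches), 100L)
  idx <- unlist(bs$batches)
  expect_true(all(idx %in% mask_entries(mask, "train")))
  pooled <- qm$values[idx]
  expect_lt(mean(pooled), mean(train_vals) - 0.1 * sd(train_vals))

  # background probability 1 removes the bias
  bs1 <- biased_batches(qm, mask, batch_size = 128, n_batches = 100,
                        p_bg = 1, seed = 4)
  pooled1 <- qm$values[unlist(bs1$batches)]
  se <- sd(train_vals) / sqrt(length(pooled1))
  expect_lt(abs(mean(pooled1) - mean(train_vals)), 5 * se)

  # a single train entry is repeated in every batch
  labels <- matrix(NA_integer_, 2, 2,
                   dimnames = list(c("P1", "P2"), c("S1", "S2")))
  labels[1, 1] <- 1L
  labels[2, 2] <- 3L
  tiny <- quant_matrix(matrix(c(1, NA, NA, 2), 2, 2,
                              dimnames = dimnames(labels)))
  m1 <- lupine:::new_partition_mask(labels, 1L, list())
  b1 <- biased_batches(tiny, m1, batch_size = 4, n_batches = 2, seed = 5)
  expect_true(all(unlist(b1$batches) == 1L))
})

test_that("partition masks serialize to TSV and back", {
  qm <- random_qm(20, 8, miss_frac = 0.3, seed = 30)
  mask <- mnar_partition(qm, val_frac = 0.15, seed = 6)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_partition_mask(mask, qm, f)
  back <- read_partition_mask(f, qm)
  expect_identical(back$labels, mask$labels)
})
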