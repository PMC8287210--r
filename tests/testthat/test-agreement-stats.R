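test_that("ROI means aggregate defined voxels per label", {
  dims <- c(4, 4, 1)
  lab <- array(0L, dim = dims)
  lab[1:2, 1, 1] <- 1L
  lab[3:4, 1, 1] <- 2L
  at <- label_atlas(lab, data.frame(id = 1:2, name = c("a", "b")))
  vals <- array(0, dim = dims)
  vals[1:2, 1, 1] <- c(0.6, 0.7)
  vals[3:4, 1, 1] <- c(1, NaN)
  rm <- roi_means(vol(array(vals, dims)), at)
  expect_equal(rm$mean, c(0.65, 1))
  # constant map: every ROI mean equals the constant
  rm2 <- roi_means(const_vol(0.42, dims = dims), at)
  expect_equal(rm2$mean, c(0.42, 0.42))
  # restriction mask can empty an ROI -> error
  restrict <- array(1, dims); restrict[3:4, 1, 1] <- 0
  expect_error(roi_means(vol(array(vals, dims)), at,
                         restrict_mask = vol(restrict)), "empty")
})

test_that("dynamic range is max minus min of group means", {
  expect_equal(dynamic_range(c(0.642, 0.688, 0.66)), 0.046)
  expect_equal(dynamic_range(rep(0.5, 4)), 0)
  expect_error(dynamic_range(0.5), "at least 2")
})

test_that("Bland-Altman bias and error match their definitions", {
  # identical vectors: exact zeros
  x <- c(0.6, 0.62, 0.64, 0.7)
  res0 <- bland_altman(x, x, dr = 0.1)
  expect_identical(res0$bias, 0)
  expect_identical(res0$error, 0)
  # delta {-1, 0, 1}: bias 0, error 1.96 * sd = 1.96
  res <- bland_altman(c(0, 1, 2), c(1, 1, 1))
  expect_equal(res$bias, 0)
  expect_equal(res$error, 1.96)
  # relative quantities against a dynamic range
  res2 <- bland_altman(c(0.6, 0.7), c(0.65, 0.73), dr = 0.046)
  expect_equal(res2$bias_dr_pct, 100 * res2$bias / 0.046)
  expect_equal(res2$error_dr_pct, 100 * res2$error / 0.046)
  expect_error(bland_altman(1:3, 1:2), "lengths")
  expect_error(bland_altman(c(1, 2), c(1, 2), dr = 0), "positive")
})

test_that("Bland-Altman equals a brute-force oracle and is antisymmetric", {
  set.seed(101)
  for (i in 1:10) {
    n <- sample(5:40, 1)
    ref <- rnorm(n, 0.66, 0.02)
    tst <- ref + rnorm(n, 0.003, 0.01)
    res <- bland_altman(ref, tst, dr = 0.05)
    d <- ref - tst
    expect_equal(res$bias, sum(d) / n)
    expect_equal(res$error,
                 1.96 * sqrt(sum((d - mean(d))^2) / (n - 1)))
    expect_equal(res$pair_mean, (ref + tst) / 2)
    swapped <- bland_altman(tst, ref, dr = 0.05)
    expect_equal(swapped$bias, -res$bias)
    expect_equal(swapped$delta, -res$delta)
    expect_equal(swapped$error, res$error)
  }
})

test_that("roi_stats_table and group summaries pool sessions correctly", {
  dims <- c(4, 2, 1)
  lab <- array(0L, dim = dims)
  lab[1:2, 1, 1] <- 1L
  lab[3:4, 1, 1] <- 2L
  at <- label_atlas(lab, data.frame(id = 1:2, name = c("a", "b")))
  mk <- function(v) const_vol(v, dims = dims)
  maps <- list(list(mk(1), mk(3)),   # subject 1, sessions 1-2
               list(mk(5), mk(7)))   # subject 2
  tab <- roi_stats_table(maps, at)
  expect_equal(nrow(tab), 8)
  pooled <- roi_group_summary(tab)
  # subject means are 2 and 6 -> group mean 4, SD across subjects
  expect_equal(pooled$mean, c(4, 4))
  expect_equal(pooled$sd, rep(sd(c(2, 6)), 2))
  per_ses <- roi_group_summary(tab, by_session = TRUE)
  expect_equal(sort(unique(per_ses$session)), 1:2)
  expect_equal(per_ses$mean[per_ses$session == 1], c(3, 3))
})

test_that("test_retest compares session group means with the stated sign", {
  dims <- c(2, 1, 1)
  lab <- array(c(1L, 2L), dim = dims)
  at <- label_atlas(lab, data.frame(id = 1:2, name = c("a", "b")))
  s1 <- list(list(vol(array(c(0.60, 0.70), dims))),
             list(vol(array(c(0.62, 0.72), dims))))
  s2 <- list(list(vol(array(c(0.59, 0.71), dims))),
             list(vol(array(c(0.61, 0.69), dims))))
  t1 <- roi_stats_table(s1, at)
  t2 <- roi_stats_table(s2, at)
  res <- test_retest(t1, t2, dr = 0.1)
  # group means: s1 = (0.61, 0.71), s2 = (0.60, 0.70): bias = +0.01
  expect_equal(res$bias, 0.01)
  ident <- test_retest(t1, t1, dr = 0.1)
  expect_identical(ident$bias, 0)
  expect_identical(ident$error, 0)
})
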