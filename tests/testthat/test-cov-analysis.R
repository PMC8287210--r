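mm_affine <- function(vox = 2) {
  aff <- diag(4); diag(aff)[1:3] <- vox; aff
}

test_that("tissue-weighted smoothing preserves constants and identity", {
  set.seed(3)
  tpm_vals <- array(runif(125, 0.3, 1), dim = c(5, 5, 5))
  tpm <- volume_map(tpm_vals, mm_affine())
  cmap <- volume_map(array(0.42, dim = c(5, 5, 5)), mm_affine())
  sm <- tissue_weighted_smooth(cmap, tpm, fwhm_mm = 6)
  defined <- is.finite(sm$values)
  expect_true(any(defined))
  expect_equal(sm$values[defined],
               rep(0.42, sum(defined)), tolerance = 1e-12)
  # FWHM 0 is the identity wherever the tissue weight is supported
  m <- volume_map(array(rnorm(125), dim = c(5, 5, 5)), mm_affine())
  id <- tissue_weighted_smooth(m, tpm, fwhm_mm = 0)
  expect_equal(id$values, m$values)
  expect_error(tissue_weighted_smooth(m, tpm, fwhm_mm = -1), "fwhm")
})

test_that("smoothing matches a hand-computed 1-D discrete kernel", {
  # 5-voxel line, 1 mm voxels, FWHM chosen so sigma = 0.5 voxel
  # (discrete kernel over offsets -2..2, mirrored at the boundaries)
  fwhm <- 0.5 * 2 * sqrt(2 * log(2))
  line <- c(1, 2, 4, 8, 16)
  m <- volume_map(array(line, dim = c(5, 1, 1)), diag(4))
  tpm <- volume_map(array(1, dim = c(5, 1, 1)), diag(4))
  sm <- tissue_weighted_smooth(m, tpm, fwhm_mm = fwhm)
  k <- exp(-0.5 * ((-2):2 / 0.5)^2); k <- k / sum(k)
  reflect <- function(i) { i <- ifelse(i < 1, 2 - i, i); ifelse(i > 5, 10 - i, i) }
  expected <- sapply(1:5, function(j) sum(k * line[reflect(j + (-2):2)]))
  expect_equal(as.vector(sm$values), expected, tolerance = 1e-12)
})

test_that("smoothing is linear in the map argument", {
  set.seed(8)
  dims <- c(6, 6, 6)
  tpm <- volume_map(array(runif(216, 0.2, 1), dims), mm_affine())
  a <- volume_map(array(rnorm(216), dims), mm_affine())
  b <- volume_map(array(rnorm(216), dims), mm_affine())
  ab <- a; ab$values <- 2 * a$values + 3 * b$values
  sa <- tissue_weighted_smooth(a, tpm, 6)
  sb <- tissue_weighted_smooth(b, tpm, 6)
  sab <- tissue_weighted_smooth(ab, tpm, 6)
  expect_equal(sab$values, 2 * sa$values + 3 * sb$values,
               tolerance = 1e-10)
})

test_that("CoV map computes 100 * SD / mean with N-1 denominator", {
  mk <- function(v) const_vol(v, dims = c(2, 2, 1))
  maps <- list(mk(0.9), mk(1.1), mk(0.9), mk(1.1))
  cm <- cov_map(maps)
  expect_equal(cm$cov$values[1, 1, 1], 100 * sd(c(0.9, 1.1, 0.9, 1.1)) / 1,
               tolerance = 1e-12)
  expect_equal(cm$cov$values[1, 1, 1], 11.547, tolerance = 1e-4)
  # identical maps: CoV 0; zero mean: undefined
  expect_true(all(cov_map(list(mk(2), mk(2)))$cov$values == 0))
  expect_true(all(is.nan(cov_map(list(mk(1), mk(-1)))$cov$values)))
  expect_error(cov_map(list(mk(1))), "at least 2")
  # invariance under global rescaling
  set.seed(4)
  rnd <- lapply(1:5, function(i)
    vol(array(runif(27, 0.5, 1), dim = c(3, 3, 3))))
  scaled <- lapply(rnd, function(m) { m$values <- 3 * m$values; m })
  expect_equal(cov_map(rnd)$cov$values, cov_map(scaled)$cov$values,
               tolerance = 1e-10)
})

test_that("CoV Bland-Altman matches a brute-force voxel oracle", {
  set.seed(31)
  dims <- c(4, 4, 4)
  ref <- vol(array(runif(64, 2, 6), dim = dims))
  tst <- vol(array(runif(64, 2, 6), dim = dims))
  tst$values[1, 1, 1] <- NaN
  res <- cov_bland_altman(ref, tst)
  joint <- is.finite(ref$values) & is.finite(tst$values)
  d <- ref$values[joint] - tst$values[joint]
  expect_equal(res$bias, mean(d))
  expect_equal(res$error, 1.96 * sd(d))
  expect_equal(res$normalizer, mean(ref$values[joint]))
  expect_equal(res$bias_dr_pct, 100 * mean(d) / mean(ref$values[joint]))
  # identical CoV maps: exact zeros; constant shift: bias only
  same <- cov_bland_altman(ref, ref)
  expect_identical(same$bias, 0)
  expect_identical(same$error, 0)
  shifted <- ref; shifted$values <- ref$values - 0.5
  sh <- cov_bland_altman(ref, shifted)
  expect_equal(sh$bias, 0.5)
  expect_equal(sh$error, 0)
  # antisymmetry of the bias under swapping
  sw <- cov_bland_altman(tst, ref)
  expect_equal(sw$bias, -res$bias)
  expect_equal(sw$error, res$error)
})
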