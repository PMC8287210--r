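test_that("SNR map scales mean-b0 by noise and b0 count", {
  expect_equal(snr_map(const_vol(60), 60, 1)$values[1], 1)
  expect_equal(snr_map(const_vol(200), 60, 12)$values[1],
               (200 / 60) * sqrt(12))
  expect_equal(snr_map(const_vol(39 * 60 / sqrt(12)), 60, 12)$values[1], 39)
  expect_error(snr_map(const_vol(1), -1), "positive")
})

test_that("group WM mask thresholds the mean tissue probability", {
  full <- group_wm_mask(list(const_vol(1), const_vol(1)), 0.95)
  expect_true(all(full$values == 1))
  # voxel with TPMs {1.0, 0.8}: mean 0.9 < 0.95 is excluded
  a <- const_vol(1); b <- const_vol(1)
  b$values[1, 1, 1] <- 0.8
  m <- group_wm_mask(list(a, b), 0.95)
  expect_identical(m$values[1, 1, 1], 0)
  expect_true(all(m$values[-1] == 1))
  # threshold 1 keeps only voxels where every TPM is 1
  m1 <- group_wm_mask(list(a, b), 1)
  expect_identical(m1$values[1, 1, 1], 0)
  expect_warning(group_wm_mask(list(const_vol(0.2)), 0.95), "empty")
})

test_that("threshold search matches hand-enumerated 8-voxel example", {
  snr <- vol(array(c(1, 1, 1, 1, 2, 2, 2, 2), dim = c(2, 2, 2)))
  icvf <- vol(array(c(1, 1, 0.5, 0.5, 1, 0.5, 0.5, 0.5), dim = c(2, 2, 2)))
  wm <- const_vol(1, dims = c(2, 2, 2))
  res <- optimize_snr_threshold(snr, icvf, wm,
                                snr_mask_config(threshold_grid = c(1, 2)))
  # t = 1: 3 of 8 ceilinged; t = 2: 1 of 4
  expect_equal(res$table$mean_ratio, c(3 / 8, 1 / 4))
  expect_equal(res$chosen_threshold, 2)
})

test_that("all-clean maps give zero ratios and the tie-break picks the
          smallest threshold", {
  snr <- vol(array(runif(27, 5, 50), dim = c(3, 3, 3)))
  icvf <- const_vol(0.6, dims = c(3, 3, 3))
  res <- optimize_snr_threshold(snr, icvf, const_vol(1, dims = c(3, 3, 3)),
                                snr_mask_config(threshold_grid = 1:4))
  expect_true(all(res$table$mean_ratio == 0))
  expect_equal(res$chosen_threshold, 1)
})

test_that("threshold search agrees with brute-force enumeration", {
  set.seed(77)
  cfg <- snr_mask_config(threshold_grid = seq(2, 40, by = 2))
  for (rep in 1:3) {
    dims <- c(8, 8, 8)
    snr_maps <- lapply(1:3, function(i)
      vol(array(runif(512, 1, 45), dim = dims)))
    icvf_maps <- lapply(1:3, function(i)
      vol(array(sample(c(0.6, 0.9995), 512, TRUE, c(0.8, 0.2)),
                dim = dims)))
    wm_arr <- array(rbinom(512, 1, 0.7), dim = dims)
    wm <- vol(wm_arr)
    res <- optimize_snr_threshold(snr_maps, icvf_maps, wm, cfg)
    # oracle: direct per-threshold, per-subject counting
    oracle <- sapply(cfg$threshold_grid, function(t) {
      mean(sapply(1:3, function(s) {
        inmask <- wm_arr == 1 & snr_maps[[s]]$values >= t
        if (!any(inmask)) return(NA_real_)
        sum(icvf_maps[[s]]$values[inmask] >= 0.999) / sum(inmask)
      }), na.rm = TRUE)
    })
    expect_equal(res$table$mean_ratio, oracle)
    expect_equal(res$chosen_threshold,
                 cfg$threshold_grid[which.min(oracle)])
  }
})

test_that("threshold search recovers a planted SNR step", {
  # SNR spans 1..80; nu_icvf ceiling exists strictly below SNR 39
  set.seed(12)
  dims <- c(10, 10, 10)
  snr_vals <- array(runif(1000, 1, 80), dim = dims)
  icvf_vals <- array(0.6, dim = dims)
  below <- snr_vals < 39
  icvf_vals[below] <- ifelse(runif(sum(below)) < 0.5, 0.9995, 0.6)
  # thresholds beyond the SNR range empty every mask and are excluded
  expect_warning(
    res <- optimize_snr_threshold(vol(snr_vals), vol(icvf_vals),
                                  const_vol(1, dims = dims),
                                  snr_mask_config()),
    "empty")
  expect_equal(res$chosen_threshold, 39)
})

test_that("raising the ceiling cutoff never increases a ratio", {
  set.seed(15)
  dims <- c(6, 6, 6)
  snr <- vol(array(runif(216, 1, 50), dim = dims))
  icvf <- vol(array(runif(216, 0.9, 1), dim = dims))
  wm <- const_vol(1, dims = dims)
  grid <- c(5, 15, 25)
  r_low <- optimize_snr_threshold(snr, icvf, wm,
    snr_mask_config(threshold_grid = grid, ceiling_cutoff = 0.95))
  r_high <- optimize_snr_threshold(snr, icvf, wm,
    snr_mask_config(threshold_grid = grid, ceiling_cutoff = 0.999))
  expect_true(all(r_high$table$mean_ratio <= r_low$table$mean_ratio))
})

test_that("ROI selection applies the complete-WM and overlap rules", {
  dims <- c(10, 10, 10)
  lab <- array(0L, dim = dims)
  lab[1:4, 1, 1] <- 1L        # fully in WM and high-SNR
  lab[1:4, 2, 1] <- 2L        # one voxel outside WM
  lab[, 3, 1] <- 3L           # 10 voxels, 9 in high-SNR (90%)
  lab[1:20] <- lab[1:20]      # no-op, keep layout explicit
  at <- label_atlas(lab, data.frame(id = 1:3,
                                    name = c("a", "b", "c")))
  wm <- array(1, dim = dims); wm[4, 2, 1] <- 0
  hs <- array(1, dim = dims); hs[10, 3, 1] <- 0
  sel <- select_rois(at, vol(wm), vol(hs), overlap_min = 0.95)
  expect_identical(sel$whole_wm_ids, c(1L, 3L))
  expect_identical(sel$high_snr_ids, 1L)
  # high-SNR set is always a subset of the whole-WM set
  expect_true(all(sel$high_snr_ids %in% sel$whole_wm_ids))
  # with a laxer overlap requirement, the 90% ROI is admitted
  sel2 <- select_rois(at, vol(wm), vol(hs), overlap_min = 0.9)
  expect_identical(sel2$high_snr_ids, c(1L, 3L))
})
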