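test_that("B1 field has unit spatial mean and bounded amplitude", {
  cfg <- small_phantom_config()
  b1 <- sample_b1_field(cfg)
  expect_equal(mean(b1$values), 1, tolerance = 1e-6)
  expect_lte(max(abs(b1$values - 1)), cfg$b1_amplitude + 1e-12)
  # deterministic given the seed
  expect_identical(sample_b1_field(cfg)$values, b1$values)
  # different subjects get different fields
  expect_false(identical(sample_b1_field(cfg, subject = 2)$values,
                         b1$values))
  # zero amplitude: constant nominal field
  flat <- sample_b1_field(small_phantom_config(b1_amplitude = 0))
  expect_true(all(flat$values == 1))
})

test_that("phantom generation is a pure function of its configuration", {
  cfg <- small_phantom_config(n_subjects = 2)
  a <- generate_phantom(cfg)
  b <- generate_phantom(cfg)
  expect_identical(a$subjects[[1]]$sessions[[2]]$mtsat_no$values,
                   b$subjects[[1]]$sessions[[2]]$mtsat_no$values)
  expect_identical(a$subjects[[2]]$sessions[[1]]$nu_icvf$values,
                   b$subjects[[2]]$sessions[[1]]$nu_icvf$values)
  expect_identical(a$truth$g$values, b$truth$g$values)
  # generation does not disturb the caller's RNG stream
  set.seed(123); before <- rnorm(1)
  set.seed(123); invisible(generate_phantom(cfg)); after <- rnorm(1)
  expect_identical(before, after)
})

test_that("sessions share ground truth but differ in noise", {
  ph <- generate_phantom(small_phantom_config(n_subjects = 1))
  s1 <- ph$subjects[[1]]$sessions[[1]]
  s2 <- ph$subjects[[1]]$sessions[[2]]
  expect_false(identical(s1$mtsat_no$values, s2$mtsat_no$values))
  expect_false(identical(s1$nu_icvf$values, s2$nu_icvf$values))
  # the noiseless component is shared: session difference is zero-mean
  expect_lt(abs(mean(s1$mtsat_no$values - s2$mtsat_no$values)), 0.01)
})

test_that("the biased MTsat map inverts the heuristic correction", {
  # MTsat_true = 1.125 under B1 = 0.9, C = 0.4 reads as 1.2 uncorrected
  biased <- apply_b1_bias(const_vol(1.125), const_vol(0.9), C = 0.4)
  expect_equal(biased$values[1], 1.2)
  ph <- generate_phantom(noiseless_phantom_config(b1_amplitude = 0.15))
  sub <- ph$subjects[[1]]
  recovered <- correct_mtsat(sub$sessions[[1]]$mtsat_no, sub$b1_true,
                             ph$config$c_factor)
  wm <- ph$truth$wm_region
  expect_equal(recovered$values[wm], ph$truth$mtsat$values[wm],
               tolerance = 1e-12)
})

test_that("mean-b0 reproduces the planted SNR profile through snr_map", {
  ph <- generate_phantom(small_phantom_config(n_subjects = 1))
  s <- ph$subjects[[1]]$sessions[[1]]
  snr <- snr_map(s$mean_b0, s$sigma, ph$config$n_b0)
  expect_equal(snr$values, ph$truth$snr$values, tolerance = 1e-12)
})

test_that("nu_icvf ceiling fraction decreases with SNR", {
  cfg <- small_phantom_config(n_subjects = 4, seed = 19)
  ph <- generate_phantom(cfg)
  low <- ph$truth$snr$values == cfg$snr_low
  frac <- function(region) mean(vapply(ph$subjects, function(sub)
    mean(sub$sessions[[1]]$nu_icvf$values[region] >= 0.999), numeric(1)))
  expect_gt(frac(low), frac(!low))
  # switching the artifact off removes ceiling voxels entirely in truth-
  # range WM (noiseless config keeps nu_icvf below the cutoff)
  ph0 <- generate_phantom(noiseless_phantom_config())
  wm <- ph0$truth$wm_region
  expect_true(all(ph0$subjects[[1]]$sessions[[1]]$nu_icvf$values[wm] < 0.999))
})

test_that("phantom writes a NIfTI tree with a complete manifest", {
  dir <- withr::local_tempdir()
  ph <- generate_phantom(small_phantom_config(n_subjects = 1,
                                              n_sessions = 1))
  manifest <- write_phantom(ph, dir)
  man <- read.delim(file.path(dir, "manifest.tsv"))
  expect_true(all(file.exists(man$path)))
  back <- read_volume(file.path(dir, "sub-01", "ses-1", "mtsat_no.nii.gz"))
  expect_equal(back$values, ph$subjects[[1]]$sessions[[1]]$mtsat_no$values)
  atlas <- read_label_atlas(file.path(dir, "atlas.nii.gz"),
                            file.path(dir, "atlas_names.tsv"))
  expect_identical(atlas$labels, ph$atlas$labels)
})

test_that("inconsistent fraction configurations are rejected", {
  expect_error(small_phantom_config(b1_amplitude = 1.2), "b1_amplitude")
  layout <- default_roi_layout(c(16L, 16L, 16L), n = c(3L, 2L, 1L))
  ids <- layout$id
  mvf <- setNames(rep(0.7, length(ids)), ids)
  avf <- setNames(rep(0.5, length(ids)), ids)
  expect_error(small_phantom_config(mvf_true = mvf, avf_true = avf))
})
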