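# Synthetic multi-subject, two-session phantom with known ground truth.
# It reproduces the statistical structure the analysis assumes: a smooth
# multiplicative B1+ field biasing MTsat, per-ROI true myelin/axon volume
# fractions, additive map noise differing between sessions, and a
# low-SNR region where the NODDI intracellular fraction hits its ceiling.

#' Default ROI layout for a phantom grid
#'
#' Places `prod(n)` disjoint box ROIs in the high-SNR zone of the grid
#' (above the low-SNR slab) and one calibration-region box inside the
#' low-SNR slab (mirroring a brainstem calibration region that sits in
#' low-SNR territory). Boxes are `(id, x0, x1, y0, y1, z0, z1)` rows.
#'
#' @param grid_shape integer vector of 3 grid dimensions (each >= 12).
#' @param n ROIs per axis, default `c(4, 3, 2)` (24 ROIs).
#' @param calib_id label id of the calibration region (default 99).
#' @return data.frame with one row per ROI box.
#' @export
default_roi_layout <- function(grid_shape, n = c(4L, 3L, 2L),
                               calib_id = 99L) {
  stopifnot(length(grid_shape) == 3L, all(grid_shape >= 12L))
  lo <- c(3L, 3L, 3L)
  hi <- grid_shape - 2L
  low_z_max <- max(3L, floor(grid_shape[3] / 4))
  zone_lo <- c(lo[1], lo[2], low_z_max + 3L)
  zone_hi <- hi
  boxes <- list()
  id <- 0L
  cell <- (zone_hi - zone_lo + 1L) %/% n
  stopifnot(all(cell >= 2L))
  for (k in seq_len(n[3])) for (j in seq_len(n[2])) for (i in seq_len(n[1])) {
    id <- id + 1L
    start <- zone_lo + c(i - 1L, j - 1L, k - 1L) * cell
    width <- pmax(2L, floor(cell * 0.7))
    boxes[[id]] <- data.frame(id = id,
      x0 = start[1], x1 = start[1] + width[1] - 1L,
      y0 = start[2], y1 = start[2] + width[2] - 1L,
      z0 = start[3], z1 = start[3] + width[3] - 1L)
  }
  # calibration region: centered in x/y, inside the low-SNR slab
  cx <- grid_shape[1] %/% 2; cy <- grid_shape[2] %/% 2
  half <- max(1L, min(3L, (cx - lo[1]) %/% 2))
  boxes[[id + 1L]] <- data.frame(id = calib_id,
    x0 = cx - half, x1 = cx + half, y0 = cy - half, y1 = cy + half,
    z0 = lo[3], z1 = low_z_max)
  do.call(rbind, boxes)
}

#' Phantom configuration
#'
#' Defines the study conditions the phantom emulates: grid and cohort
#' size, per-ROI ground-truth myelin/axon volume fractions, the
#' MTsat-to-MVF constant, the transmit-field amplitude and smoothness,
#' the error amplitude of the surrogate data-driven field, map noise,
#' and the SNR profile driving the intracellular-fraction ceiling
#' artifact.
#'
#' @param grid_shape 3 integers (default 32x32x32, 2 mm isotropic).
#' @param n_subjects number of subjects (default 25).
#' @param n_sessions sessions per subject (default 2).
#' @param roi_layout data.frame as from [default_roi_layout()].
#' @param mvf_true named per-ROI true myelin volume fractions; default
#'   an anti-correlated ramp over 0.445..0.408 across ROIs, with the
#'   calibration region at 0.3623.
#' @param avf_true named per-ROI true axon volume fractions; default a
#'   ramp over 0.308..0.384, calibration region 0.30.
#' @param alpha_true true MTsat-to-MVF constant (default 0.25 p.u.^-1).
#' @param c_factor transmit-correction constant used to bias MTsat
#'   (default 0.4).
#' @param b1_amplitude maximum deviation of the transmit field from
#'   nominal (default 0.2, i.e. +/-20\%).
#' @param b1_poly_order polynomial order of the field (default 2).
#' @param un_error_amplitude amplitude of the smooth error field added
#'   to the true field to form the surrogate data-driven estimate
#'   (default 0.05).
#' @param map_noise_sd named per-session additive Gaussian noise SDs for
#'   `mtsat` (p.u.), `nu_icvf`, `nu_iso`.
#' @param nu_iso_range range the per-ROI free-water fraction is drawn
#'   from (default `c(0.02, 0.12)`).
#' @param snr_high,snr_low SNR plateau values outside/inside the low-SNR
#'   slab (defaults 60 and 20).
#' @param sigma_noise scalar b0 noise estimate (default 50) from which
#'   the mean-b0 volume is constructed so that [snr_map()] reproduces
#'   the SNR profile exactly.
#' @param n_b0 number of b0 images (default 12).
#' @param ceiling_prob_fn monotone-decreasing function of SNR giving the
#'   per-voxel probability that nu_icvf is replaced by a ceiling value
#'   >= 0.999; default `0.5 * exp(-SNR / 13)`.
#' @param wm_background_mvf,wm_background_avf true fractions in WM
#'   voxels outside any ROI.
#' @param seed integer RNG seed; the full dataset is a pure function of
#'   the configuration including this seed.
#' @return A list of class `phantom_config`.
#' @export
phantom_config <- function(grid_shape = c(32L, 32L, 32L),
                           n_subjects = 25L,
                           n_sessions = 2L,
                           roi_layout = default_roi_layout(grid_shape),
                           mvf_true = NULL,
                           avf_true = NULL,
                           alpha_true = 0.25,
                           c_factor = 0.4,
                           b1_amplitude = 0.2,
                           b1_poly_order = 2L,
                           un_error_amplitude = 0.05,
                           map_noise_sd = c(mtsat = 0.08, nu_icvf = 0.02,
                                            nu_iso = 0.01),
                           nu_iso_range = c(0.02, 0.12),
                           snr_high = 60, snr_low = 20,
                           sigma_noise = 50, n_b0 = 12L,
                           ceiling_prob_fn = function(snr)
                             pmin(1, 0.5 * exp(-snr / 13)),
                           wm_background_mvf = 0.42,
                           wm_background_avf = 0.34,
                           seed = 1L) {
  grid_shape <- as.integer(grid_shape)
  stopifnot(length(grid_shape) == 3L, all(grid_shape >= 12L),
            n_subjects >= 1L, n_sessions >= 1L,
            b1_amplitude >= 0, b1_amplitude < 1,
            un_error_amplitude >= 0, c_factor >= 0, c_factor < 1,
            alpha_true > 0, sigma_noise > 0, n_b0 >= 1L)
  ids <- roi_layout$id
  calib_id <- 99L
  if (!calib_id %in% ids)
    calib_id <- ids[length(ids)]
  noncal <- setdiff(ids, calib_id)
  if (is.null(mvf_true)) {
    mvf_true <- stats::setNames(
      seq(0.445, 0.408, length.out = length(noncal)), noncal)
    mvf_true[as.character(calib_id)] <- 0.3623
  }
  if (is.null(avf_true)) {
    avf_true <- stats::setNames(
      seq(0.308, 0.384, length.out = length(noncal)), noncal)
    avf_true[as.character(calib_id)] <- 0.30
  }
  stopifnot(all(mvf_true > 0 & mvf_true < 1),
            all(avf_true > 0 & avf_true < 1),
            all(mvf_true[as.character(ids)] +
                  avf_true[as.character(ids)] < 1))
  # ROI disjointness
  occ <- array(0L, dim = grid_shape)
  for (r in seq_len(nrow(roi_layout))) {
    b <- roi_layout[r, ]
    occ[b$x0:b$x1, b$y0:b$y1, b$z0:b$z1] <-
      occ[b$x0:b$x1, b$y0:b$y1, b$z0:b$z1] + 1L
  }
  if (any(occ > 1L)) stop("ROI boxes overlap")
  structure(list(grid_shape = grid_shape, n_subjects = as.integer(n_subjects),
                 n_sessions = as.integer(n_sessions),
                 roi_layout = roi_layout, calib_id = calib_id,
                 mvf_true = mvf_true, avf_true = avf_true,
                 alpha_true = alpha_true, c_factor = c_factor,
                 b1_amplitude = b1_amplitude,
                 b1_poly_order = as.integer(b1_poly_order),
                 un_error_amplitude = un_error_amplitude,
                 map_noise_sd = map_noise_sd,
                 nu_iso_range = nu_iso_range,
                 snr_high = snr_high, snr_low = snr_low,
                 sigma_noise = sigma_noise, n_b0 = as.integer(n_b0),
                 ceiling_prob_fn = ceiling_prob_fn,
                 wm_background_mvf = wm_background_mvf,
                 wm_background_avf = wm_background_avf,
                 seed = as.integer(seed)),
            class = "phantom_config")
}

.phantom_affine <- function(grid_shape, voxel_mm = 2) {
  aff <- diag(4)
  diag(aff)[1:3] <- voxel_mm
  aff[1:3, 4] <- -voxel_mm * (grid_shape - 1) / 2
  aff
}

# Normalized coordinates in [-1, 1]^3 for each axis, as arrays.
.norm_coords <- function(grid_shape) {
  lapply(1:3, function(ax) {
    v <- if (grid_shape[ax] > 1)
      seq(-1, 1, length.out = grid_shape[ax]) else 0
    a <- array(0, dim = grid_shape)
    idx <- slice.index(a, ax)
    array(v[idx], dim = grid_shape)
  })
}

# Random polynomial field of given order on [-1,1]^3; coefficients drawn
# from the current RNG stream. Returns a centered (mean ~ 0) array.
.random_poly_field <- function(grid_shape, order = 2L) {
  co <- .norm_coords(grid_shape)
  terms <- list()
  for (p1 in 0:order) for (p2 in 0:order) for (p3 in 0:order) {
    deg <- p1 + p2 + p3
    if (deg == 0L || deg > order) next
    terms[[length(terms) + 1L]] <- co[[1]]^p1 * co[[2]]^p2 * co[[3]]^p3
  }
  coefs <- stats::rnorm(length(terms))
  f <- Reduce(`+`, Map(`*`, terms, coefs))
  f - mean(f)
}

# Deterministic dome: high at the grid center, falling towards the edges
# (the typical transmit profile of a head coil at 3T).
.dome_field <- function(grid_shape) {
  co <- .norm_coords(grid_shape)
  f <- 1 - (co[[1]]^2 + co[[2]]^2 + co[[3]]^2) / 3
  f - mean(f)
}

# Center to spatial mean zero and rescale max |f| to amplitude.
.center_scale <- function(f, amplitude) {
  f <- f - mean(f)
  m <- max(abs(f))
  if (m > 0 && amplitude > 0) f * (amplitude / m) else f * 0
}

#' Sample a smooth transmit-field map
#'
#' The field is a fixed dome component (center-high quadratic, the
#' typical transmit profile of a head coil) plus a random low-order
#' polynomial perturbation, centered to spatial mean 1.0 and scaled so
#' that `max |B1 - 1| = b1_amplitude`. Deterministic given
#' `config$seed` (plus `subject` offsetting the stream so each subject
#' gets its own field).
#'
#' @param config a [phantom_config()].
#' @param subject subject index (default 1) selecting the random
#'   component.
#' @return B1+ [volume_map], fraction of nominal.
#' @export
sample_b1_field <- function(config, subject = 1L) {
  stopifnot(inherits(config, "phantom_config"))
  if (config$b1_amplitude >= 1) stop("'b1_amplitude' must be < 1")
  f <- .with_seed(config$seed + 7919L * as.integer(subject), {
    dome <- .dome_field(config$grid_shape)
    rnd <- .random_poly_field(config$grid_shape, config$b1_poly_order)
    rs <- max(abs(rnd))
    if (rs > 0) rnd <- rnd / rs
    ds <- max(abs(dome))
    if (ds > 0) dome <- dome / ds
    .center_scale(dome + 0.5 * rnd, config$b1_amplitude)
  })
  volume_map(1 + f, affine = .phantom_affine(config$grid_shape),
             unit = "fraction of nominal")
}

# Fill an array with per-ROI values plus a WM background, NaN outside WM.
.paint_rois <- function(config, roi_values, background, outside = NaN) {
  arr <- array(outside, dim = config$grid_shape)
  wm <- .wm_region(config)
  arr[wm] <- background
  for (r in seq_len(nrow(config$roi_layout))) {
    b <- config$roi_layout[r, ]
    arr[b$x0:b$x1, b$y0:b$y1, b$z0:b$z1] <-
      roi_values[as.character(b$id)]
  }
  arr
}

# Logical array: the WM slab (margin-2 interior of the grid).
.wm_region <- function(config) {
  d <- config$grid_shape
  wm <- array(FALSE, dim = d)
  wm[3:(d[1] - 2L), 3:(d[2] - 2L), 3:(d[3] - 2L)] <- TRUE
  wm
}

# Logical array: the low-SNR slab (bottom quarter of z within the grid).
.low_snr_region <- function(config) {
  d <- config$grid_shape
  low <- array(FALSE, dim = d)
  zmax <- max(3L, floor(d[3] / 4))
  low[, , 1:zmax] <- TRUE
  low
}

#' Generate a synthetic phantom dataset
#'
#' Builds the full aligned dataset for `n_subjects` x `n_sessions`:
#' uncorrected MTsat (true MTsat = MVF_true / alpha_true, biased by the
#' subject's B1+ field via the inverse heuristic correction, plus
#' session noise), NODDI maps (nu_icvf = AWF_true / (1 - nu_iso) with
#' AWF_true = AVF_true / (1 - MVF_true); ceiling replacement in low-SNR
#' voxels), a surrogate data-driven B1+ map (true field plus an
#' independent smooth error field), a mean-b0 volume consistent with the
#' SNR profile, and shared ground truth (atlas, WM TPM, calibration
#' mask, true MVF/AVF/g maps). Ground truth is identical across sessions
#' and subjects; noise realizations differ per subject and session. The
#' whole dataset is a pure function of the configuration (including its
#' seed).
#'
#' @param config a [phantom_config()].
#' @return A list of class `phantom_dataset` with elements `subjects`
#'   (nested per-subject/session maps), `atlas`, `wm_tpm`, `calib_mask`,
#'   `truth`, `config`.
#' @export
generate_phantom <- function(config = phantom_config()) {
  stopifnot(inherits(config, "phantom_config"))
  d <- config$grid_shape
  aff <- .phantom_affine(d)
  ids <- config$roi_layout$id
  wm <- .wm_region(config)
  low <- .low_snr_region(config)

  # --- shared ground truth ---------------------------------------------
  mvf_t <- .paint_rois(config, config$mvf_true, config$wm_background_mvf)
  avf_t <- .paint_rois(config, config$avf_true, config$wm_background_avf)
  # non-WM voxels: plausible non-tissue values for the measured maps
  mtsat_t <- mvf_t / config$alpha_true
  mtsat_t[!wm] <- 0.1
  awf_t <- avf_t / (1 - mvf_t)
  if (any(is.finite(awf_t) & awf_t > 1))
    stop("inconsistent config: true AWF exceeds 1")
  truth <- .with_seed(config$seed, {
    nu_iso_roi <- stats::setNames(
      stats::runif(length(ids), config$nu_iso_range[1],
                   config$nu_iso_range[2]), ids)
    nu_iso_t <- .paint_rois(config, nu_iso_roi,
                            mean(config$nu_iso_range))
    nu_iso_t[!wm] <- 0.8
    nu_icvf_t <- awf_t / (1 - nu_iso_t)
    nu_icvf_t[!wm] <- 0.1
    list(nu_iso = nu_iso_t, nu_icvf = nu_icvf_t)
  })
  nu_iso_t <- truth$nu_iso
  nu_icvf_t <- truth$nu_icvf
  if (any(nu_icvf_t[wm] > 1))
    stop("inconsistent config: true nu_icvf exceeds 1 in WM")
  g_t <- sqrt(avf_t / (mvf_t + avf_t))

  labels <- array(0L, dim = d)
  for (r in seq_len(nrow(config$roi_layout))) {
    b <- config$roi_layout[r, ]
    labels[b$x0:b$x1, b$y0:b$y1, b$z0:b$z1] <- b$id
  }
  nm <- data.frame(id = ids,
                   name = ifelse(ids == config$calib_id,
                                 "calibration_region",
                                 sprintf("wm_roi_%02d", ids)))
  atlas <- label_atlas(labels, nm, affine = aff)
  tpm_vals <- wm + 0
  wm_tpm <- volume_map(tpm_vals, aff, unit = "probability")
  calib_mask <- volume_map((labels == config$calib_id) + 0, aff,
                           unit = "binary")

  snr_true <- array(config$snr_high, dim = d)
  snr_true[low] <- config$snr_low
  mean_b0_vals <- snr_true * config$sigma_noise / sqrt(config$n_b0)
  p_ceiling <- config$ceiling_prob_fn(snr_true)

  vmap <- function(vals, unit = "") volume_map(vals, aff, unit)
  sd_ <- config$map_noise_sd

  subjects <- .with_seed(config$seed + 1L, {
    lapply(seq_len(config$n_subjects), function(s) {
      b1 <- sample_b1_field(config, subject = s)
      err <- .center_scale(.random_poly_field(d, config$b1_poly_order),
                           config$un_error_amplitude)
      b1_sur <- vmap(b1$values + err, "fraction of nominal")
      mtsat_no_clean <- mtsat_t * (1 - config$c_factor * b1$values) /
        (1 - config$c_factor)
      sessions <- lapply(seq_len(config$n_sessions), function(ses) {
        mtsat_no <- mtsat_no_clean +
          stats::rnorm(length(mtsat_t), 0, sd_[["mtsat"]])
        nu_icvf <- nu_icvf_t +
          stats::rnorm(length(nu_icvf_t), 0, sd_[["nu_icvf"]])
        nu_iso <- nu_iso_t +
          stats::rnorm(length(nu_iso_t), 0, sd_[["nu_iso"]])
        # ceiling artifact: low-SNR voxels jump to >= 0.999
        hit <- stats::runif(length(nu_icvf)) < as.vector(p_ceiling)
        nu_icvf[hit] <- stats::runif(sum(hit), 0.999, 1)
        # measured fractions are clamped to their physical range
        nu_icvf <- pmin(pmax(nu_icvf, 0), 1)
        nu_iso <- pmin(pmax(nu_iso, 0), 1)
        list(mtsat_no = vmap(array(mtsat_no, d), "p.u."),
             nu_icvf = vmap(array(nu_icvf, d), "fraction"),
             nu_iso = vmap(array(nu_iso, d), "fraction"),
             odi = vmap(array(0.3, d), "dimensionless"),
             mean_b0 = vmap(mean_b0_vals, "a.u."),
             sigma = config$sigma_noise)
      })
      list(sessions = sessions, b1_true = b1, b1_surrogate = b1_sur)
    })
  })

  structure(list(
    subjects = subjects,
    atlas = atlas,
    wm_tpm = wm_tpm,
    calib_mask = calib_mask,
    truth = list(mvf = vmap(mvf_t, "fraction"),
                 avf = vmap(avf_t, "fraction"),
                 awf = vmap(awf_t, "fraction"),
                 g = vmap(g_t, "dimensionless"),
                 mtsat = vmap(mtsat_t, "p.u."),
                 nu_icvf = vmap(nu_icvf_t, "fraction"),
                 nu_iso = vmap(nu_iso_t, "fraction"),
                 snr = vmap(snr_true, "dimensionless"),
                 wm_region = wm),
    config = config),
    class = "phantom_dataset")
}

#' @export
print.phantom_dataset <- function(x, ...) {
  cfg <- x$config
  cat(sprintf(paste0("<phantom_dataset> %d subject(s) x %d session(s), ",
                     "grid %d x %d x %d, %d ROI(s)\n"),
              cfg$n_subjects, cfg$n_sessions, cfg$grid_shape[1],
              cfg$grid_shape[2], cfg$grid_shape[3],
              nrow(cfg$roi_layout)))
  invisible(x)
}

#' Write a phantom dataset to a NIfTI directory tree
#'
#' One folder per subject/session with the per-session maps, shared
#' ground-truth volumes under `truth/`, the atlas and masks at the top
#' level, and a manifest TSV listing every written file.
#'
#' @param dataset a `phantom_dataset`.
#' @param dir output directory (created if needed).
#' @return Path to the manifest TSV, invisibly.
#' @export
write_phantom <- function(dataset, dir) {
  stopifnot(inherits(dataset, "phantom_dataset"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list()
  add <- function(subject, session, kind, path)
    manifest[[length(manifest) + 1L]] <<-
      data.frame(subject = subject, session = session, kind = kind,
                 path = path)
  for (s in seq_along(dataset$subjects)) {
    sub <- dataset$subjects[[s]]
    sdir <- file.path(dir, sprintf("sub-%02d", s))
    dir.create(sdir, showWarnings = FALSE)
    write_volume(sub$b1_true, file.path(sdir, "b1_true.nii.gz"))
    add(s, NA, "b1_true", file.path(sdir, "b1_true.nii.gz"))
    write_volume(sub$b1_surrogate, file.path(sdir, "b1_surrogate.nii.gz"))
    add(s, NA, "b1_surrogate", file.path(sdir, "b1_surrogate.nii.gz"))
    for (ses in seq_along(sub$sessions)) {
      sesd <- file.path(sdir, sprintf("ses-%d", ses))
      dir.create(sesd, showWarnings = FALSE)
      maps <- sub$sessions[[ses]]
      for (kind in c("mtsat_no", "nu_icvf", "nu_iso", "odi", "mean_b0")) {
        p <- file.path(sesd, paste0(kind, ".nii.gz"))
        write_volume(maps[[kind]], p)
        add(s, ses, kind, p)
      }
      writeLines(as.character(maps$sigma), file.path(sesd, "sigma.txt"))
      add(s, ses, "sigma", file.path(sesd, "sigma.txt"))
    }
  }
  tdir <- file.path(dir, "truth")
  dir.create(tdir, showWarnings = FALSE)
  for (kind in c("mvf", "avf", "awf", "g", "mtsat", "nu_icvf", "nu_iso",
                 "snr")) {
    p <- file.path(tdir, paste0(kind, ".nii.gz"))
    write_volume(dataset$truth[[kind]], p)
    add(NA, NA, paste0("truth_", kind), p)
  }
  write_label_atlas(dataset$atlas, file.path(dir, "atlas.nii.gz"),
                    file.path(dir, "atlas_names.tsv"))
  add(NA, NA, "atlas", file.path(dir, "atlas.nii.gz"))
  write_volume(dataset$wm_tpm, file.path(dir, "wm_tpm.nii.gz"))
  add(NA, NA, "wm_tpm", file.path(dir, "wm_tpm.nii.gz"))
  write_volume(dataset$calib_mask, file.path(dir, "calib_mask.nii.gz"))
  add(NA, NA, "calib_mask", file.path(dir, "calib_mask.nii.gz"))
  man <- do.call(rbind, manifest)
  mp <- file.path(dir, "manifest.tsv")
  utils::write.table(man, mp, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(mp)
}
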