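# SNR-based masking: low SNR in diffusion data drives a ceiling artifact
# in the NODDI intracellular fraction (nu_icvf -> 1), so the analysis is
# restricted to white matter with sufficient SNR.

#' SNR mask configuration
#'
#' @param n_b0 number of non-diffusion-weighted (b0) images averaged into
#'   the mean-b0 volume (default 12).
#' @param ceiling_cutoff nu_icvf value at or above which a voxel counts
#'   as artifactual (default 0.999).
#' @param threshold_grid strictly increasing candidate SNR thresholds
#'   (default integers 1..80).
#' @param wm_group_threshold group WM tissue-probability threshold
#'   (default 0.95).
#' @param roi_overlap_min minimum fraction of an ROI's voxels inside the
#'   high-SNR mask for high-SNR ROI membership (default 0.95).
#' @return A list of class `snr_mask_config`.
#' @export
snr_mask_config <- function(n_b0 = 12L, ceiling_cutoff = 0.999,
                            threshold_grid = 1:80,
                            wm_group_threshold = 0.95,
                            roi_overlap_min = 0.95) {
  stopifnot(n_b0 >= 1L, ceiling_cutoff > 0, ceiling_cutoff <= 1,
            all(diff(threshold_grid) > 0), all(threshold_grid > 0),
            wm_group_threshold > 0, wm_group_threshold <= 1,
            roi_overlap_min >= 0, roi_overlap_min <= 1)
  structure(list(n_b0 = as.integer(n_b0), ceiling_cutoff = ceiling_cutoff,
                 threshold_grid = threshold_grid,
                 wm_group_threshold = wm_group_threshold,
                 roi_overlap_min = roi_overlap_min),
            class = "snr_mask_config")
}

#' Voxel-wise SNR map from a mean-b0 volume
#'
#' \eqn{SNR = (\bar{b_0} / \sigma) \sqrt{n_{b0}}}: the mean b0 image
#' divided by a single scalar noise estimate and scaled by the square
#' root of the number of averaged b0 images.
#'
#' @param mean_b0 mean b0 [volume_map].
#' @param sigma scalar noise estimate (> 0), e.g. the average SD within a
#'   noise region outside the head.
#' @param n_b0 number of b0 images (>= 1).
#' @return SNR [volume_map] (dimensionless).
#' @export
snr_map <- function(mean_b0, sigma, n_b0 = 12L) {
  stopifnot(inherits(mean_b0, "volume_map"))
  if (!is.numeric(sigma) || length(sigma) != 1L || sigma <= 0)
    stop("'sigma' must be a positive scalar")
  if (n_b0 < 1L) stop("'n_b0' must be >= 1")
  out <- mean_b0
  out$values <- (mean_b0$values / sigma) * sqrt(n_b0)
  out$unit <- "dimensionless"
  out
}

#' Group white-matter mask from tissue probability maps
#'
#' Averages the per-subject WM tissue probability maps and thresholds the
#' mean at `threshold` (mask where mean >= threshold).
#'
#' @param tpms list of WM-TPM [volume_map]s.
#' @param threshold probability threshold in `(0, 1]`.
#' @return Binary [volume_map] (1 = WM).
#' @export
group_wm_mask <- function(tpms, threshold = 0.95) {
  if (inherits(tpms, "volume_map")) tpms <- list(tpms)
  stopifnot(length(tpms) >= 1L, threshold > 0, threshold <= 1)
  for (t in tpms[-1]) .assert_compatible(tpms[[1]], t, what = "TPMs")
  acc <- Reduce(`+`, lapply(tpms, function(t) t$values)) / length(tpms)
  out <- tpms[[1]]
  out$values <- (acc >= threshold) + 0
  if (!any(out$values == 1)) warning("group WM mask is empty")
  out$unit <- "binary"
  out
}

#' Optimize the SNR threshold against the nu_icvf ceiling artifact
#'
#' For each candidate threshold `t`, every subject contributes the ratio
#' of artifactual voxels (nu_icvf >= `ceiling_cutoff`) to total voxels in
#' the mask `wm_mask & (SNR >= t)`. The chosen threshold minimizes the
#' group-mean ratio; ties resolve to the smallest threshold (retaining as
#' many voxels as possible). Candidates that empty a subject's mask drop
#' that subject; candidates emptying all masks are excluded with a
#' warning.
#'
#' @param snr_maps list of per-subject SNR [volume_map]s.
#' @param nu_icvf_maps list of per-subject nu_icvf [volume_map]s, paired
#'   with `snr_maps`.
#' @param wm_mask binary WM [volume_map].
#' @param cfg an [snr_mask_config()].
#' @return A list of class `threshold_search_result` with the search
#'   `table` (threshold, mean_ratio, sd_ratio, n_subjects) and
#'   `chosen_threshold`.
#' @export
optimize_snr_threshold <- function(snr_maps, nu_icvf_maps, wm_mask,
                                   cfg = snr_mask_config()) {
  if (inherits(snr_maps, "volume_map")) snr_maps <- list(snr_maps)
  if (inherits(nu_icvf_maps, "volume_map")) nu_icvf_maps <- list(nu_icvf_maps)
  stopifnot(length(snr_maps) == length(nu_icvf_maps),
            length(snr_maps) >= 1L)
  wm <- .as_logical_mask(wm_mask)
  grid <- cfg$threshold_grid
  n_sub <- length(snr_maps)
  ratios <- matrix(NA_real_, nrow = length(grid), ncol = n_sub)
  for (s in seq_len(n_sub)) {
    .assert_compatible(snr_maps[[s]], nu_icvf_maps[[s]],
                       what = "SNR and nu_icvf maps")
    snr <- snr_maps[[s]]$values[wm]
    art <- nu_icvf_maps[[s]]$values[wm] >= cfg$ceiling_cutoff
    art[is.na(art)] <- FALSE
    for (k in seq_along(grid)) {
      inmask <- is.finite(snr) & snr >= grid[k]
      n_tot <- sum(inmask)
      if (n_tot > 0L) ratios[k, s] <- sum(art & inmask) / n_tot
    }
  }
  n_contrib <- rowSums(!is.na(ratios))
  mean_ratio <- rowMeans(ratios, na.rm = TRUE)
  sd_ratio <- apply(ratios, 1L, stats::sd, na.rm = TRUE)
  mean_ratio[n_contrib == 0L] <- NA_real_
  if (any(n_contrib == 0L))
    warning(sum(n_contrib == 0L),
            " candidate threshold(s) empty every subject's mask; excluded")
  tab <- data.frame(threshold = grid, mean_ratio = mean_ratio,
                    sd_ratio = sd_ratio, n_subjects = n_contrib)
  valid <- which(!is.na(mean_ratio))
  if (length(valid) == 0L) stop("no candidate threshold yields a non-empty mask")
  chosen <- grid[valid[which.min(mean_ratio[valid])]]  # which.min: first min
  structure(list(table = tab, chosen_threshold = chosen),
            class = "threshold_search_result")
}

#' High-SNR mask
#'
#' Intersection of the WM mask with `SNR >= threshold`.
#'
#' @param wm_mask binary WM [volume_map].
#' @param snr SNR [volume_map].
#' @param threshold SNR threshold.
#' @return Binary [volume_map].
#' @export
high_snr_mask <- function(wm_mask, snr, threshold) {
  .assert_compatible(wm_mask, snr, what = "WM mask and SNR map")
  out <- wm_mask
  keep <- .as_logical_mask(wm_mask) & is.finite(snr$values) &
    snr$values >= threshold
  out$values <- keep + 0
  out$unit <- "binary"
  out
}

#' Select analysis ROIs from an atlas
#'
#' Whole-WM ROIs are atlas labels whose voxels lie completely inside the
#' group WM mask; high-SNR ROIs are the subset whose fraction of voxels
#' inside the high-SNR mask is at least `overlap_min` (a voxel-count
#' fraction of the ROI, not a Dice coefficient).
#'
#' @param atlas a [label_atlas].
#' @param wm_mask binary WM [volume_map].
#' @param high_snr binary high-SNR [volume_map].
#' @param overlap_min minimum overlap fraction (default 0.95).
#' @return A list with `whole_wm_ids`, `high_snr_ids`, and a per-ROI
#'   `table` (id, name, n_voxels, in_whole_wm, overlap_frac, in_high_snr).
#' @export
select_rois <- function(atlas, wm_mask, high_snr, overlap_min = 0.95) {
  stopifnot(inherits(atlas, "label_atlas"))
  lab <- as.vector(atlas$labels)
  if (!any(lab != 0L)) stop("atlas has no labeled voxels")
  wm <- as.vector(.as_logical_mask(wm_mask))
  hs <- as.vector(.as_logical_mask(high_snr))
  ids <- sort(unique(lab[lab != 0L]))
  n_vox <- vapply(ids, function(i) sum(lab == i), numeric(1))
  in_wm_frac <- vapply(ids, function(i) mean(wm[lab == i]), numeric(1))
  hs_frac <- vapply(ids, function(i) mean(hs[lab == i]), numeric(1))
  in_whole <- in_wm_frac == 1
  in_high <- in_whole & hs_frac >= overlap_min
  nm <- atlas$names$name[match(ids, atlas$names$id)]
  tab <- data.frame(id = ids, name = nm, n_voxels = n_vox,
                    in_whole_wm = in_whole, overlap_frac = hs_frac,
                    in_high_snr = in_high)
  list(whole_wm_ids = ids[in_whole], high_snr_ids = ids[in_high],
       table = tab)
}
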