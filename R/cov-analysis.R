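# Tissue-weighted smoothing and coefficient-of-variation analysis across
# subjects/sessions, plus voxel-wise Bland-Altman comparison of CoV maps
# between correction variants.

# 1-D Gaussian convolution matrix with reflective boundaries.
# n: line length; sigma_vox: SD in voxel units.
.gauss_conv_matrix <- function(n, sigma_vox) {
  if (sigma_vox <= 0) return(diag(n))
  half <- max(1L, ceiling(4 * sigma_vox))
  offs <- (-half):half
  k <- exp(-0.5 * (offs / sigma_vox)^2)
  k <- k / sum(k)
  K <- matrix(0, n, n)
  for (j in seq_len(n)) {
    idx <- j + offs
    # reflect indices at the boundaries (mirror without repeating the edge
    # period beyond one fold; adequate for kernels shorter than the line)
    idx <- ifelse(idx < 1L, 2L - idx, idx)
    idx <- ifelse(idx > n, 2L * n - idx, idx)
    idx <- pmin(pmax(idx, 1L), n)
    for (t in seq_along(idx)) K[idx[t], j] <- K[idx[t], j] + k[t]
  }
  t(K)
}

# Separable 3-D Gaussian smoothing of an array (no NA handling here).
.gauss_smooth3d <- function(arr, sigma_vox) {
  d <- dim(arr)
  stopifnot(length(d) == 3L, length(sigma_vox) == 3L)
  # axis 1
  K1 <- .gauss_conv_matrix(d[1], sigma_vox[1])
  m <- K1 %*% matrix(arr, nrow = d[1])
  arr <- array(m, dim = d)
  # axis 2
  K2 <- .gauss_conv_matrix(d[2], sigma_vox[2])
  arr <- aperm(arr, c(2, 1, 3))
  m <- K2 %*% matrix(arr, nrow = d[2])
  arr <- aperm(array(m, dim = d[c(2, 1, 3)]), c(2, 1, 3))
  # axis 3
  K3 <- .gauss_conv_matrix(d[3], sigma_vox[3])
  arr <- aperm(arr, c(3, 1, 2))
  m <- K3 %*% matrix(arr, nrow = d[3])
  aperm(array(m, dim = d[c(3, 1, 2)]), c(2, 3, 1))
}

.voxel_sizes <- function(affine) {
  sqrt(colSums(affine[1:3, 1:3]^2))
}

#' Tissue-weighted Gaussian smoothing
#'
#' Smooths a quantitative map while confining the spatial support to a
#' tissue class: \eqn{G * (map \cdot tpm) / G * (tpm)} with `G` a
#' Gaussian kernel of the stated full width at half maximum (converted
#' to a per-axis sigma via the voxel sizes from the affine). This avoids
#' blending non-tissue values (e.g. CSF) into the tissue estimate at
#' boundaries. Voxels where the smoothed tissue weight falls below
#' `support_cutoff` are undefined in the output. Undefined input voxels
#' contribute zero weight. Boundary handling is reflective.
#'
#' @param map a [volume_map].
#' @param tpm tissue probability [volume_map] in `[0, 1]`.
#' @param fwhm_mm kernel FWHM in millimetres (>= 0; 0 is the identity on
#'   supported voxels).
#' @param support_cutoff minimum smoothed tissue weight (default 0.05).
#' @return Smoothed [volume_map].
#' @export
tissue_weighted_smooth <- function(map, tpm, fwhm_mm = 6,
                                   support_cutoff = 0.05) {
  .assert_compatible(map, tpm, what = "map and TPM")
  if (fwhm_mm < 0) stop("'fwhm_mm' must be >= 0")
  vox <- .voxel_sizes(map$affine)
  sigma_vox <- (fwhm_mm / (2 * sqrt(2 * log(2)))) / vox
  w <- tpm$values
  w[!is.finite(map$values)] <- 0
  w[!is.finite(w)] <- 0
  mv <- map$values
  mv[!is.finite(mv)] <- 0
  num <- .gauss_smooth3d(mv * w, sigma_vox)
  den <- .gauss_smooth3d(w, sigma_vox)
  out <- map
  vals <- num / den
  vals[den < support_cutoff] <- NaN
  out$values <- vals
  out
}

#' Voxel-wise coefficient of variation across maps
#'
#' For a set of grid-compatible maps (all subjects and sessions of one
#' metric/variant), computes voxel-wise \eqn{CoV = 100 \cdot SD / mean}
#' (sample SD, N-1 denominator) within a mask. Voxels with fewer than 2
#' defined contributions or non-positive mean are undefined.
#'
#' @param maps list of >= 2 [volume_map]s.
#' @param mask binary [volume_map] restricting the computation.
#' @param metric,variant,fwhm_mm optional tags stored on the result.
#' @return A list of class `cov_map`: `cov` ([volume_map], percent),
#'   `n_contributing` (integer array), plus the tags.
#' @export
cov_map <- function(maps, mask = NULL, metric = NULL, variant = NULL,
                    fwhm_mm = NULL) {
  if (length(maps) < 2L) stop("need at least 2 maps for a CoV")
  for (m in maps[-1]) .assert_compatible(maps[[1]], m, what = "maps")
  d <- dim(maps[[1]]$values)
  stack <- vapply(maps, function(m) as.vector(m$values),
                  numeric(prod(d)))
  def <- is.finite(stack)
  n <- rowSums(def)
  sx <- rowSums(ifelse(def, stack, 0))
  sx2 <- rowSums(ifelse(def, stack^2, 0))
  mu <- sx / n
  var_ <- (sx2 - n * mu^2) / (n - 1)
  var_[var_ < 0] <- 0  # numeric guard
  cov <- 100 * sqrt(var_) / mu
  cov[n < 2L | !is.finite(mu) | mu <= 0] <- NaN
  if (!is.null(mask)) {
    keep <- as.vector(.as_logical_mask(mask))
    cov[!keep] <- NaN
  }
  out <- maps[[1]]
  out$values <- array(cov, dim = d)
  out$unit <- "percent"
  structure(list(cov = out, n_contributing = array(n, dim = d),
                 metric = metric, variant = variant, fwhm_mm = fwhm_mm),
            class = "cov_map")
}

#' Voxel-wise Bland-Altman comparison of two CoV maps
#'
#' Per-voxel differences \eqn{\delta_v = CoV_{ref,v} - CoV_{test,v}} over
#' the jointly defined voxels; bias and error as in [bland_altman()].
#' Relative quantities are normalized by the mean of the reference CoV
#' over the jointly defined voxels (the reference variant's typical CoV
#' level), not by a dynamic range.
#'
#' @param cov_ref,cov_test `cov_map` objects (or CoV [volume_map]s) on
#'   the same grid.
#' @return An `agreement_result` with `normalizer` set to the reference
#'   CoV mean; `bias_dr_pct`/`error_dr_pct` hold the normalized
#'   percentages.
#' @export
cov_bland_altman <- function(cov_ref, cov_test) {
  ref <- if (inherits(cov_ref, "cov_map")) cov_ref$cov else cov_ref
  tst <- if (inherits(cov_test, "cov_map")) cov_test$cov else cov_test
  .assert_compatible(ref, tst, what = "CoV maps")
  joint <- is.finite(ref$values) & is.finite(tst$values)
  if (!any(joint)) stop("CoV maps have no jointly defined voxels")
  r <- ref$values[joint]
  t_ <- tst$values[joint]
  res <- bland_altman(r, t_, dr = NULL)
  normalizer <- mean(r)
  res$normalizer <- normalizer
  if (is.finite(normalizer) && normalizer > 0) {
    res$bias_dr_pct <- 100 * res$bias / normalizer
    res$error_dr_pct <- 100 * res$error / normalizer
  }
  res
}
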