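# Voxel-wise g-ratio mapping: MVF from calibrated MTsat, AWF/AVF from
# NODDI compartments, and the aggregate g-ratio g = sqrt(AVF/(AVF+MVF)).

.count_out_of_range <- function(values, lo = 0, hi = 1, tol = 0) {
  sum(is.finite(values) & (values < lo - tol | values > hi + tol))
}

#' Myelin volume fraction from MTsat
#'
#' Voxel-wise \eqn{MVF_{MR} = \alpha \cdot MTsat}. Values outside
#' `[0, 1]` (possible with noisy MTsat) are counted and reported via a
#' warning but not clipped unless `clip = TRUE`.
#'
#' @param mtsat MTsat [volume_map] (percent units).
#' @param alpha calibration constant (p.u.^-1), > 0.
#' @param clip clamp the result into `[0, 1]`.
#' @param warn warn about out-of-range voxels.
#' @return MVF [volume_map] (fraction).
#' @export
compute_mvf <- function(mtsat, alpha, clip = FALSE, warn = TRUE) {
  stopifnot(inherits(mtsat, "volume_map"),
            is.numeric(alpha), length(alpha) == 1L, alpha > 0)
  out <- mtsat
  out$values <- alpha * mtsat$values
  n_bad <- .count_out_of_range(out$values)
  if (n_bad > 0L && warn)
    warning(n_bad, " MVF voxel(s) outside [0, 1]",
            if (clip) " (clipped)" else " (not clipped)")
  if (clip) out$values <- pmin(pmax(out$values, 0), 1)
  out$unit <- "fraction"
  out
}

#' Axonal water fraction from NODDI compartments
#'
#' Voxel-wise \eqn{AWF = (1 - \nu_{iso}) \nu_{icvf}}.
#'
#' @param nu_icvf intracellular volume fraction [volume_map].
#' @param nu_iso isotropic (free-water) volume fraction [volume_map].
#' @param tol tolerated excursion of the inputs beyond `[0, 1]` before
#'   erroring.
#' @return AWF [volume_map] (fraction).
#' @export
compute_awf <- function(nu_icvf, nu_iso, tol = 1e-6) {
  .assert_compatible(nu_icvf, nu_iso, what = "NODDI maps")
  for (nm in c("nu_icvf", "nu_iso")) {
    v <- get(nm)$values
    n_bad <- .count_out_of_range(v, tol = tol)
    if (n_bad > 0L)
      stop(nm, " has ", n_bad, " voxel(s) outside [0, 1]")
  }
  out <- nu_icvf
  out$values <- (1 - nu_iso$values) * nu_icvf$values
  out$unit <- "fraction"
  out
}

#' Axon volume fraction
#'
#' Voxel-wise \eqn{AVF_{MR} = (1 - \alpha \cdot MTsat)(1 - \nu_{iso})
#' \nu_{icvf}}, i.e. `(1 - MVF) * AWF`: the axonal water fraction scaled
#' by the non-myelin share of the voxel.
#'
#' @inheritParams compute_mvf
#' @inheritParams compute_awf
#' @return AVF [volume_map] (fraction).
#' @export
compute_avf <- function(mtsat, alpha, nu_icvf, nu_iso, clip = FALSE,
                        warn = TRUE) {
  mvf <- compute_mvf(mtsat, alpha, clip = clip, warn = warn)
  .assert_compatible(mtsat, nu_icvf, what = "MTsat and NODDI maps")
  awf <- compute_awf(nu_icvf, nu_iso)
  out <- mvf
  out$values <- (1 - mvf$values) * awf$values
  out$unit <- "fraction"
  out
}

#' Aggregate MR g-ratio
#'
#' Voxel-wise \eqn{g_{MR} = \sqrt{1 - MVF/(MVF + AVF)} =
#' \sqrt{AVF/(MVF + AVF)}}, ranging from 0 (no axon) to 1 (no myelin).
#' Voxels with `MVF = AVF = 0` are undefined (`NaN`). The ratio stays in
#' `[0, 1]` whenever both inputs are non-negative, so `g` is always real
#' there; negative inputs beyond `tol` are an error.
#'
#' @param mvf MVF [volume_map].
#' @param avf AVF [volume_map].
#' @param tol tolerated negativity of inputs before erroring.
#' @return g-ratio [volume_map] (dimensionless).
#' @export
compute_g <- function(mvf, avf, tol = 1e-6) {
  .assert_compatible(mvf, avf, what = "MVF and AVF maps")
  for (nm in c("mvf", "avf")) {
    v <- get(nm)$values
    n_bad <- sum(is.finite(v) & v < -tol)
    if (n_bad > 0L) stop(nm, " has ", n_bad, " negative voxel(s)")
  }
  total <- mvf$values + avf$values
  ratio <- avf$values / total
  ratio[is.finite(total) & total == 0] <- NaN
  out <- mvf
  out$values <- sqrt(pmin(pmax(ratio, 0), 1))
  out$unit <- "dimensionless"
  out
}

#' Full g-ratio voxel set for one MTsat map
#'
#' Convenience wrapper computing MVF, AWF, AVF and g in one pass.
#'
#' @inheritParams compute_avf
#' @param variant_tag optional correction-variant tag carried along.
#' @return A list of class `gratio_voxel_set` with elements `mvf`, `awf`,
#'   `avf`, `g`, `alpha`, `variant_tag`.
#' @export
compute_gratio_set <- function(mtsat, alpha, nu_icvf, nu_iso, clip = FALSE,
                               warn = FALSE, variant_tag = NULL) {
  mvf <- compute_mvf(mtsat, alpha, clip = clip, warn = warn)
  awf <- compute_awf(nu_icvf, nu_iso)
  avf <- mvf
  avf$values <- (1 - mvf$values) * awf$values
  g <- compute_g(mvf, avf)
  structure(list(mvf = mvf, awf = awf, avf = avf, g = g, alpha = alpha,
                 variant_tag = variant_tag),
            class = "gratio_voxel_set")
}
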