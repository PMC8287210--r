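#' Construct a fiber table
#'
#' Histological fiber records: inner axon radius `r`, myelin sheath
#' thickness `m` (same length units), and a positive count per row, so a
#' table can hold per-fiber rows (`count = 1`) or binned histogram rows.
#'
#' @param r inner axon radii (> 0).
#' @param m myelin sheath thicknesses (>= 0).
#' @param count fiber counts per row (>= 1), recycled.
#' @return A data.frame of class `fiber_table`.
#' @export
fiber_table <- function(r, m, count = 1L) {
  ft <- data.frame(r = as.numeric(r), m = as.numeric(m),
                   count = as.numeric(count))
  if (nrow(ft) == 0L) stop("fiber table is empty")
  if (any(!is.finite(ft$r)) || any(ft$r <= 0)) stop("radii must be positive")
  if (any(!is.finite(ft$m)) || any(ft$m < 0))
    stop("myelin thickness must be non-negative")
  if (any(ft$count < 1)) stop("counts must be >= 1")
  class(ft) <- c("fiber_table", "data.frame")
  ft
}

#' Read a fiber table from TSV
#'
#' Expects columns `r` and `m`, optionally `count` (default 1).
#'
#' @param path TSV file path.
#' @return A [fiber_table].
#' @export
read_fiber_table <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("r", "m") %in% colnames(d)))
    stop("fiber TSV must have columns 'r' and 'm'")
  if (is.null(d$count)) d$count <- 1L
  fiber_table(d$r, d$m, d$count)
}

#' Histological myelin volume fraction from a fiber table
#'
#' Computes the cross-sectional volume budget of a histological sample of
#' myelinated fibers and derives the myelin volume fraction:
#' \itemize{
#'   \item myelinated-axon area \eqn{TAV_m = \sum count \cdot \pi r^2}
#'   \item myelin area \eqn{TMV = \sum count \cdot \pi (r+m)^2 - TAV_m}
#'   \item unmyelinated-axon area \eqn{TAV_u = u \cdot TAV_m}, with the
#'     unmyelinated fraction `u` defaulting to 0.43 (the common report of
#'     unmyelinated axons as 30\% of total axonal volume corresponds to
#'     0.3/(1-0.3) = 43\% of the myelinated-axon volume)
#'   \item total volume \eqn{TV = (TAV_m + TAV_u + TMV) / (1 - EVF)} with
#'     the extracellular volume fraction `EVF` defaulting to 0.25
#'   \item \eqn{MVF_{hist} = TMV / TV}.
#' }
#'
#' @param fibers a [fiber_table].
#' @param unmyelinated_frac unmyelinated-axon area as a fraction of the
#'   myelinated-axon area (>= 0).
#' @param evf_frac extracellular volume fraction in `[0, 1)`.
#' @return An object of class `calibration_result` with elements
#'   `mvf_hist`, `tav_m`, `tmv`, `tav_u`, `tev`, `tv`.
#' @export
mvf_from_histology <- function(fibers, unmyelinated_frac = 0.43,
                               evf_frac = 0.25) {
  if (!inherits(fibers, "fiber_table"))
    fibers <- fiber_table(fibers$r, fibers$m,
                          if (is.null(fibers$count)) 1L else fibers$count)
  if (unmyelinated_frac < 0) stop("'unmyelinated_frac' must be >= 0")
  if (evf_frac < 0 || evf_frac >= 1) stop("'evf_frac' must be in [0, 1)")
  tav_m <- sum(fibers$count * pi * fibers$r^2)
  tmv <- sum(fibers$count * pi * (fibers$r + fibers$m)^2) - tav_m
  tav_u <- unmyelinated_frac * tav_m
  tv <- (tav_m + tav_u + tmv) / (1 - evf_frac)
  tev <- evf_frac * tv
  structure(list(mvf_hist = tmv / tv, tav_m = tav_m, tmv = tmv,
                 tav_u = tav_u, tev = tev, tv = tv,
                 unmyelinated_frac = unmyelinated_frac,
                 evf_frac = evf_frac),
            class = "calibration_result")
}

#' @export
print.calibration_result <- function(x, ...) {
  cat("<calibration_result>\n")
  if (!is.null(x$mvf_hist))
    cat(sprintf("  MVF_hist = %.4f (TMV/TV)\n", x$mvf_hist))
  if (!is.null(x$alpha))
    cat(sprintf("  alpha = %.4f p.u.^-1 (group-mean MTsat %.4f p.u.)%s\n",
                x$alpha, x$mean_mtsat,
                if (is.null(x$variant_tag)) "" else
                  paste0(" [", x$variant_tag, "]")))
  invisible(x)
}

#' Calibrate the MTsat-to-MVF proportionality constant
#'
#' The MR myelin volume fraction is modeled as proportional to MTsat
#' without intercept, \eqn{MVF_{MR} = \alpha \cdot MTsat}. Given a
#' histology-anchored `mvf_hist` for a calibration region, alpha is the
#' ratio of `mvf_hist` to the group-average MTsat in that region. The
#' group average is the unweighted mean of per-subject/session ROI means,
#' pooling all supplied maps (both sessions of every subject). One alpha
#' is computed per correction variant; after calibration, the group-mean
#' MVF inside the calibration region equals `mvf_hist` for every variant
#' by construction.
#'
#' @param mvf_hist scalar histological myelin volume fraction, or a
#'   `calibration_result` from [mvf_from_histology()].
#' @param mtsat_maps list of MTsat [volume_map]s (all subjects/sessions
#'   of one variant).
#' @param calib_roi binary [volume_map] of the calibration region.
#' @param variant_tag optional tag recorded in the result.
#' @return A `calibration_result` with elements `alpha`, `mean_mtsat`,
#'   `mvf_hist`, `variant_tag`.
#' @export
calibrate_alpha <- function(mvf_hist, mtsat_maps, calib_roi,
                            variant_tag = NULL) {
  if (inherits(mvf_hist, "calibration_result")) mvf_hist <- mvf_hist$mvf_hist
  stopifnot(is.numeric(mvf_hist), length(mvf_hist) == 1L, mvf_hist > 0)
  if (inherits(mtsat_maps, "volume_map")) mtsat_maps <- list(mtsat_maps)
  means <- vapply(mtsat_maps, masked_mean, numeric(1), mask = calib_roi)
  mean_mtsat <- mean(means)
  if (!is.finite(mean_mtsat) || mean_mtsat <= 0)
    stop("group-mean MTsat in the calibration region is not positive")
  structure(list(alpha = mvf_hist / mean_mtsat, mean_mtsat = mean_mtsat,
                 mvf_hist = mvf_hist, variant_tag = variant_tag),
            class = "calibration_result")
}
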