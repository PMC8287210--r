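#' Normalize a B1+ map to fraction-of-nominal units
#'
#' B1+ maps are expected as fraction of the nominal flip angle (1.0 =
#' nominal, typical range 0.7-1.3). Maps supplied in percent-of-nominal
#' (values around 100) are auto-detected via their median of defined
#' voxels exceeding 10 and divided by 100, with a warning.
#'
#' @param b1 a [volume_map] of the relative transmit field.
#' @return A [volume_map] in fraction-of-nominal units.
#' @export
normalize_b1 <- function(b1) {
  stopifnot(inherits(b1, "volume_map"))
  med <- stats::median(b1$values[is.finite(b1$values)])
  if (is.finite(med) && med > 10) {
    warning("B1+ map looks like percent-of-nominal (median ", signif(med, 4),
            "); dividing by 100")
    b1$values <- b1$values / 100
  }
  b1$unit <- "fraction of nominal"
  b1
}

#' Multiplicative factor of the heuristic B1+ correction
#'
#' The heuristic correction multiplies the uncorrected MTsat by
#' \eqn{(1 - C) / (1 - C \cdot B_1^+)}, with the semi-empirical constant
#' `C` calibrated for the MT pulse (0.4 for the protocol this pipeline
#' targets; it may need recalibration for other MT pulses, so it is
#' always an argument, never hard-coded).
#'
#' @param b1 a [volume_map] of the relative transmit field (fraction of
#'   nominal; percent inputs are auto-rescaled).
#' @param C correction constant in `[0, 1)`.
#' @return A [volume_map] of the voxel-wise correction factor.
#' @export
bias_factor <- function(b1, C = 0.4) {
  stopifnot(inherits(b1, "volume_map"))
  if (!is.numeric(C) || length(C) != 1L || C < 0 || C >= 1)
    stop("'C' must be a scalar in [0, 1)")
  b1 <- normalize_b1(b1)
  den <- 1 - C * b1$values
  bad <- is.finite(den) & den <= 0
  if (any(bad))
    stop(sum(bad), " voxel(s) have 1 - C*B1 <= 0; B1+ map is implausible")
  out <- b1
  out$values <- (1 - C) / den
  out$unit <- "dimensionless"
  out
}

#' Correct an MTsat map for transmit-field inhomogeneity
#'
#' Applies the heuristic voxel-wise correction
#' \deqn{MTsat_{corr} = MTsat_{uncorr} \frac{1 - C}{1 - C \cdot B_1^+}}
#' Voxels where the B1+ field is undefined become undefined (`NaN`) in
#' the output. Implausible B1+ values are propagated, never silently
#' clipped; a non-positive denominator is an error reporting the
#' offending voxel count.
#'
#' @param mtsat_no uncorrected MTsat [volume_map] (percent units).
#' @param b1 relative transmit-field [volume_map].
#' @param C correction constant, default 0.4.
#' @param tol grid tolerance passed to [check_compatible()].
#' @return Corrected MTsat [volume_map].
#' @export
correct_mtsat <- function(mtsat_no, b1, C = 0.4, tol = 1e-4) {
  stopifnot(inherits(mtsat_no, "volume_map"))
  .assert_compatible(mtsat_no, b1, tol, what = "MTsat and B1 maps")
  fac <- bias_factor(b1, C)
  out <- mtsat_no
  out$values <- mtsat_no$values * fac$values
  out
}

#' Simulate the transmit-field bias on a true MTsat map
#'
#' Inverse of [correct_mtsat()]: given the bias-free MTsat, returns the
#' map an uncorrected reconstruction would yield under the field `b1`,
#' i.e. \eqn{MTsat_{true} (1 - C \cdot B_1^+) / (1 - C)}. Composing with
#' [correct_mtsat()] recovers the input to machine precision.
#'
#' @param mtsat_true bias-free MTsat [volume_map].
#' @param b1 relative transmit-field [volume_map].
#' @param C correction constant.
#' @return Biased (uncorrected-equivalent) MTsat [volume_map].
#' @export
apply_b1_bias <- function(mtsat_true, b1, C = 0.4) {
  stopifnot(inherits(mtsat_true, "volume_map"))
  .assert_compatible(mtsat_true, b1, what = "MTsat and B1 maps")
  fac <- bias_factor(b1, C)
  out <- mtsat_true
  out$values <- mtsat_true$values / fac$values
  out
}

#' Correction-variant tags
#'
#' The pipeline compares three MTsat correction variants: `REFERENCE_B1`
#' (measured B1+ field map), `NONE` (no correction), and `DATA_DRIVEN`
#' (field estimated from the data itself). `NONE` carries no B1 source;
#' the other two require one.
#'
#' @param tag one of `"REFERENCE_B1"`, `"NONE"`, `"DATA_DRIVEN"`.
#' @param b1_source a B1+ [volume_map], or `NULL` for `NONE`.
#' @return An object of class `correction_variant`.
#' @export
correction_variant <- function(tag, b1_source = NULL) {
  tag <- match.arg(tag, c("REFERENCE_B1", "NONE", "DATA_DRIVEN"))
  if (tag == "NONE" && !is.null(b1_source))
    stop("variant NONE must not carry a B1 source")
  if (tag != "NONE" && is.null(b1_source))
    stop("variant ", tag, " requires a B1 source")
  structure(list(tag = tag, b1_source = b1_source),
            class = "correction_variant")
}

#' Apply a correction variant to an uncorrected MTsat map
#'
#' @param mtsat_no uncorrected MTsat [volume_map].
#' @param variant a [correction_variant].
#' @param C correction constant.
#' @return MTsat [volume_map] under that variant.
#' @export
apply_variant <- function(mtsat_no, variant, C = 0.4) {
  stopifnot(inherits(variant, "correction_variant"))
  if (variant$tag == "NONE") return(mtsat_no)
  correct_mtsat(mtsat_no, variant$b1_source, C)
}
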