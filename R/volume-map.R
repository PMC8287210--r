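#' Construct a volume map
#'
#' A `volume_map` is the carrier for every voxel-wise quantity in the
#' pipeline (MTsat, B1+, nu_icvf, nu_iso, MVF, AVF, g, SNR, tissue
#' probability, CoV): a 3-D numeric grid plus a 4x4 voxel-to-world affine.
#' Undefined voxels are encoded as `NaN`; zero is a legal data value
#' (MTsat near 0 occurs in CSF), so it is never used as a missing marker.
#'
#' @param values numeric 3-D array.
#' @param affine 4x4 numeric voxel-to-world transform (last row 0 0 0 1).
#' @param unit free-text unit label (e.g. "p.u.", "fraction").
#' @return An object of class `volume_map` with elements `values`,
#'   `affine`, `unit`.
#' @export
volume_map <- function(values, affine = diag(4), unit = "") {
  if (!is.array(values) || length(dim(values)) != 3L)
    stop("'values' must be a 3-D array")
  if (any(dim(values) < 1L))
    stop("all three grid dimensions must be >= 1")
  affine <- as.matrix(affine)
  if (!identical(dim(affine), c(4L, 4L)))
    stop("'affine' must be a 4x4 matrix")
  values <- array(as.double(values), dim = dim(values))  # strip foreign attrs
  structure(list(values = values, affine = affine, unit = as.character(unit)),
            class = "volume_map")
}

#' @export
print.volume_map <- function(x, ...) {
  d <- dim(x$values)
  nundef <- sum(!is.finite(x$values))
  cat(sprintf("<volume_map> %d x %d x %d", d[1], d[2], d[3]))
  if (nzchar(x$unit)) cat(sprintf(" [%s]", x$unit))
  cat(sprintf("; %d undefined voxel(s)\n", nundef))
  rng <- range(x$values[is.finite(x$values)])
  cat(sprintf("  defined range: [%g, %g]\n", rng[1], rng[2]))
  invisible(x)
}

#' Read a NIfTI volume
#'
#' Reads a NIfTI-1/2 image as a [volume_map]. 4-D images whose trailing
#' axes are singletons are squeezed to 3-D; any other dimensionality is an
#' error (this pipeline operates strictly on aligned 3-D maps).
#'
#' @param path path to a `.nii` or `.nii.gz` file.
#' @param unit optional unit label to attach.
#' @return A [volume_map].
#' @export
read_volume <- function(path, unit = "") {
  if (!file.exists(path)) stop("file not found: ", path)
  img <- RNifti::readNifti(path)
  vals <- as.array(img)
  d <- dim(vals)
  if (length(d) > 3L) {
    if (all(d[-(1:3)] == 1L)) {
      dim(vals) <- d[1:3]
    } else {
      stop("image is ", length(d), "-D with non-singleton trailing axes: ", path)
    }
  }
  if (length(dim(vals)) != 3L)
    stop("image is not 3-D after squeezing: ", path)
  volume_map(vals, affine = unclass(RNifti::xform(img)), unit = unit)
}

#' Write a volume to NIfTI
#'
#' @param map a [volume_map].
#' @param path output path (`.nii` or `.nii.gz`).
#' @param datatype NIfTI on-disk datatype; the default `"double"` makes
#'   write/read round-trips bit-exact.
#' @return `path`, invisibly.
#' @export
write_volume <- function(map, path, datatype = "double") {
  stopifnot(inherits(map, "volume_map"))
  img <- RNifti::asNifti(map$values, datatype = datatype)
  img <- RNifti::`sform<-`(img, structure(map$affine, code = 2L))
  RNifti::writeNifti(img, path, datatype = datatype)
  invisible(path)
}

#' Grid compatibility of two volumes
#'
#' Two maps are grid-compatible iff their shapes are equal and their
#' affines agree elementwise within `tol` (world units). All maps entering
#' one analysis must share one grid; no resampling is performed here
#' (spatial registration is assumed done upstream).
#'
#' @param a,b [volume_map]s.
#' @param tol absolute tolerance on affine entries.
#' @return `TRUE` or `FALSE`.
#' @export
check_compatible <- function(a, b, tol = 1e-4) {
  stopifnot(inherits(a, "volume_map"), inherits(b, "volume_map"))
  identical(dim(a$values), dim(b$values)) &&
    all(abs(a$affine - b$affine) <= tol)
}

.assert_compatible <- function(a, b, tol = 1e-4, what = "maps") {
  if (!check_compatible(a, b, tol))
    stop(what, " are not grid-compatible (shape or affine mismatch)")
  invisible(TRUE)
}

.as_logical_mask <- function(mask) {
  v <- if (inherits(mask, "volume_map")) mask$values else mask
  m <- !is.na(v) & !is.nan(v) & v != 0
  m
}

#' Mean of a map over a binary mask
#'
#' Arithmetic mean of the map over foreground mask voxels, skipping
#' undefined (`NaN`) voxels.
#'
#' @param map a [volume_map].
#' @param mask a binary [volume_map] (nonzero = foreground).
#' @return scalar mean.
#' @export
masked_mean <- function(map, mask) {
  stopifnot(inherits(map, "volume_map"))
  if (inherits(mask, "volume_map")) .assert_compatible(map, mask)
  m <- .as_logical_mask(mask)
  if (!any(m)) stop("mask has no foreground voxels")
  vals <- map$values[m]
  vals <- vals[is.finite(vals)]
  if (length(vals) == 0L) stop("all masked values are undefined")
  mean(vals)
}

#' Construct a label atlas
#'
#' Integer ROI label image plus an id-to-name table. Label 0 is background
#' and needs no name entry; every nonzero id present in the grid must have
#' one.
#'
#' @param labels integer 3-D array.
#' @param names data.frame with columns `id`, `name`.
#' @param affine 4x4 voxel-to-world transform.
#' @return An object of class `label_atlas`.
#' @export
label_atlas <- function(labels, names, affine = diag(4)) {
  if (!is.array(labels) || length(dim(labels)) != 3L)
    stop("'labels' must be a 3-D array")
  storage.mode(labels) <- "integer"
  names <- as.data.frame(names)
  if (!all(c("id", "name") %in% colnames(names)))
    stop("'names' must have columns 'id' and 'name'")
  present <- setdiff(sort(unique(as.vector(labels))), 0L)
  missing <- setdiff(present, names$id)
  if (length(missing))
    stop("label id(s) without a name entry: ", paste(missing, collapse = ", "))
  structure(list(labels = labels, names = names, affine = as.matrix(affine)),
            class = "label_atlas")
}

#' @export
print.label_atlas <- function(x, ...) {
  d <- dim(x$labels)
  cat(sprintf("<label_atlas> %d x %d x %d; %d ROI(s)\n",
              d[1], d[2], d[3], nrow(x$names)))
  invisible(x)
}

#' Read a label atlas (integer NIfTI + name table)
#'
#' @param path NIfTI file of integer labels.
#' @param names_path two-column TSV (`id`, `name`).
#' @return A [label_atlas].
#' @export
read_label_atlas <- function(path, names_path) {
  vol <- read_volume(path)
  labels <- vol$values
  if (max(abs(labels - round(labels)), na.rm = TRUE) > 1e-6)
    stop("atlas image contains non-integer labels")
  labels <- array(as.integer(round(labels)), dim = dim(labels))
  nm <- utils::read.delim(names_path, stringsAsFactors = FALSE)
  label_atlas(labels, nm, affine = vol$affine)
}

#' Write a label atlas
#'
#' @param atlas a [label_atlas].
#' @param path NIfTI output path.
#' @param names_path TSV output path for the name table.
#' @return `path`, invisibly.
#' @export
write_label_atlas <- function(atlas, path, names_path) {
  img <- RNifti::asNifti(atlas$labels, datatype = "int32")
  img <- RNifti::`sform<-`(img, structure(atlas$affine, code = 2L))
  RNifti::writeNifti(img, path, datatype = "int32")
  utils::write.table(atlas$names, names_path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

# Evaluate an expression under a fixed RNG state, restoring the caller's.
.with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}
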