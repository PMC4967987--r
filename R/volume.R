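#' CT image volume
#'
#' Container for a scalar CT voxel grid.  Intensities are attenuation values
#' in Hounsfield Units (HU); a single slice is stored as a volume of depth 1.
#' The optional lung mask marks the voxels eligible for clustering and
#' evaluation (typically the output of a lung-isolation preprocessing step,
#' which this package does not perform itself).
#'
#' The array layout is rows x cols x slices, with 1-based `(row, col, slice)`
#' coordinates throughout the package.
#'
#' @param voxels numeric matrix (one slice) or 3D array of intensities in HU.
#'   All values must be finite.
#' @param spacing physical voxel size in mm, length 3 `(row, col, slice)`.
#' @param lung_mask optional logical matrix/array of the same shape; `TRUE`
#'   marks voxels that participate in clustering.  `NULL` means all voxels.
#' @return An object of class `ct_volume`: a list with elements `voxels`
#'   (3D array), `spacing`, and `lung_mask` (3D logical array or `NULL`).
#' @examples
#' v <- ct_volume(matrix(c(-850, -850, -50, 40), 2, 2))
#' dim(v$voxels)
#' @export
ct_volume <- function(voxels, spacing = c(1, 1, 1), lung_mask = NULL) {
  if (is.matrix(voxels)) dim(voxels) <- c(dim(voxels), 1L)
  if (!is.array(voxels) || length(dim(voxels)) != 3L)
    stop_param("voxels must be a matrix or a 3D array (rows x cols x slices)")
  if (!is.numeric(voxels) || !all(is.finite(voxels)))
    stop_param("voxel intensities must be finite numbers")
  storage.mode(voxels) <- "double"
  if (!is.numeric(spacing) || length(spacing) != 3L || any(spacing <= 0))
    stop_param("spacing must be 3 positive numbers (mm)")
  if (!is.null(lung_mask)) {
    if (is.matrix(lung_mask)) dim(lung_mask) <- c(dim(lung_mask), 1L)
    if (!identical(dim(lung_mask), dim(voxels)))
      stop_param("lung_mask shape %s does not match voxels %s",
                 paste(dim(lung_mask), collapse = "x"),
                 paste(dim(voxels), collapse = "x"))
    lung_mask <- array(as.logical(lung_mask), dim(voxels))
    if (anyNA(lung_mask)) stop_param("lung_mask must be logical with no NA")
  }
  structure(list(voxels = voxels, spacing = as.numeric(spacing),
                 lung_mask = lung_mask),
            class = "ct_volume")
}

#' @export
print.ct_volume <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf("ct_volume: %d x %d x %d voxels, spacing %s mm\n",
              d[1], d[2], d[3], paste(format(x$spacing), collapse = " x ")))
  cat(sprintf("  intensity range [%.1f, %.1f] HU\n",
              min(x$voxels), max(x$voxels)))
  if (!is.null(x$lung_mask))
    cat(sprintf("  lung mask: %d of %d voxels eligible\n",
                sum(x$lung_mask), length(x$lung_mask)))
  invisible(x)
}

as_ct_volume <- function(x) {
  if (inherits(x, "ct_volume")) x else ct_volume(x)
}

# Linear indices (column-major) of the voxels that participate in clustering.
eligible_index <- function(volume) {
  if (is.null(volume$lung_mask)) seq_along(volume$voxels)
  else which(volume$lung_mask)
}

# Logical indicator array of eligible voxels.
eligible_array <- function(volume) {
  if (is.null(volume$lung_mask)) array(TRUE, dim(volume$voxels))
  else volume$lung_mask
}

# Extract slice s of a volume as a depth-1 ct_volume.
volume_slice <- function(volume, s) {
  ct_volume(volume$voxels[, , s, drop = FALSE], volume$spacing,
            if (is.null(volume$lung_mask)) NULL
            else volume$lung_mask[, , s, drop = FALSE])
}
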