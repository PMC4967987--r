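#' Neighborhood window specification
#'
#' Defines the voxel window used by the spatially regularized algorithms.  A
#' 2D window is a `size x size` square confined to the voxel's own slice; a
#' 3D window is a rectangular prism `size x size x depth` that also spans
#' neighboring slices (with `depth = 3`, the slice the voxel belongs to plus
#' the previous and following slice).  Windows are truncated at the volume
#' boundary: spatial sums only ever reference in-bounds voxels, and neighbor
#' counts reflect the actual truncated window.
#'
#' @param mode `"2d"` or `"3d"`.
#' @param size odd in-plane window side, >= 1.
#' @param depth odd window extent along the slice axis (3D mode only);
#'   defaults to `size`.
#' @param include_center should the centre voxel itself be part of the
#'   window?  The SKFCM penalty window excludes it; the SFCM/MSKFCM spatial
#'   function includes it by default.
#' @return An object of class `neighborhood_spec`.
#' @examples
#' neighborhood_spec("3d", size = 3)   # 3 x 3 x 3 prism, 27 voxels
#' @export
neighborhood_spec <- function(mode = c("2d", "3d"), size = 3L, depth = NULL,
                              include_center = TRUE) {
  mode <- match.arg(mode)
  if (!is_count(size) || size < 1 || size %% 2 == 0)
    stop_param("window size must be an odd integer >= 1 (got %s)",
               format(size))
  if (is.null(depth)) depth <- if (mode == "3d") size else 1L
  if (!is_count(depth) || depth < 1 || depth %% 2 == 0)
    stop_param("window depth must be an odd integer >= 1 (got %s)",
               format(depth))
  if (mode == "2d" && depth != 1L)
    stop_param("a 2D window cannot span slices (depth must be 1)")
  structure(list(mode = mode, size = as.integer(size),
                 depth = as.integer(depth),
                 include_center = isTRUE(include_center)),
            class = "neighborhood_spec")
}

#' @export
print.neighborhood_spec <- function(x, ...) {
  cat(sprintf("%s window %dx%d%s, centre %s\n", toupper(x$mode),
              x$size, x$size,
              if (x$mode == "3d") sprintf("x%d", x$depth) else "",
              if (x$include_center) "included" else "excluded"))
  invisible(x)
}

# Window extent along (row, col, slice).
window_dims <- function(spec) {
  c(spec$size, spec$size, if (spec$mode == "3d") spec$depth else 1L)
}

#' Enumerate a voxel's neighborhood
#'
#' Returns the coordinates of the window centred on `voxel`, truncated at the
#' volume boundary.  In 2D mode the window never crosses slice boundaries.
#'
#' @param volume a [ct_volume()] (or array coercible to one).
#' @param voxel integer coordinate `(row, col, slice)`, 1-based.
#' @param spec a [neighborhood_spec()].
#' @return integer matrix with columns `row`, `col`, `slice`, one row per
#'   in-bounds window voxel (centre excluded when `include_center` is FALSE).
#' @examples
#' v <- ct_volume(array(0, c(5, 5, 1)))
#' nrow(extract_neighborhood(v, c(3, 3, 1), neighborhood_spec("2d", 3)))  # 9
#' nrow(extract_neighborhood(v, c(1, 1, 1), neighborhood_spec("2d", 3)))  # 4
#' @export
extract_neighborhood <- function(volume, voxel, spec) {
  volume <- as_ct_volume(volume)
  stopifnot(inherits(spec, "neighborhood_spec"))
  d <- dim(volume$voxels)
  voxel <- as.integer(voxel)
  if (length(voxel) != 3L || any(voxel < 1L) || any(voxel > d))
    stop_param("voxel (%s) lies outside the volume (%s)",
               paste(voxel, collapse = ","), paste(d, collapse = "x"))
  w <- window_dims(spec)
  h <- (w - 1L) %/% 2L
  off <- expand.grid(row = seq.int(-h[1L], h[1L]),
                     col = seq.int(-h[2L], h[2L]),
                     slice = seq.int(-h[3L], h[3L]))
  coords <- cbind(row = voxel[1L] + off$row,
                  col = voxel[2L] + off$col,
                  slice = voxel[3L] + off$slice)
  keep <- coords[, 1L] >= 1L & coords[, 1L] <= d[1L] &
          coords[, 2L] >= 1L & coords[, 2L] <= d[2L] &
          coords[, 3L] >= 1L & coords[, 3L] <= d[3L]
  if (!spec$include_center)
    keep <- keep & !(coords[, 1L] == voxel[1L] & coords[, 2L] == voxel[2L] &
                     coords[, 3L] == voxel[3L])
  coords[keep, , drop = FALSE]
}

# Per-voxel window sum of a scalar field (full 3D array), respecting the
# eligibility mask: ineligible voxels contribute nothing and the caller can
# obtain actual neighbor counts by summing the mask indicator.
masked_box_sum <- function(field, spec) {
  w <- window_dims(spec)
  box_sum(field, w[1L], w[2L], w[3L], include_center = spec$include_center)
}
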