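#' Synthetic CT phantom specification
#'
#' Describes a CT-like test volume: an elliptical "lung" region of
#' air-filled parenchyma (default -850 HU) embedded in chest-wall tissue
#' (default 40 HU), containing bright vessel tubes (default 30 HU) and
#' spherical nodules of midrange attenuation (default -50 HU), plus
#' additive Gaussian noise.  The defaults (64 x 64 x 3 voxels, one radius-4
#' nodule, two vessels, noise sd 20 HU) give intensity populations separated
#' well beyond the noise scale, while staying small enough for fast tests;
#' every field is overridable.
#'
#' @param shape integer `(rows, cols, slices)`.
#' @param background_hu lung parenchyma mean (HU).
#' @param tissue_hu chest-wall mean outside the lung ellipse (HU).
#' @param nodules list of `list(center = c(row, col, slice), radius, hu)`;
#'   radius in voxels (>= 1).  Spheres must lie inside the lung region.
#'   `NULL` (default) places one midrange-HU nodule scaled to the shape;
#'   `list()` means no nodules.
#' @param vessels list of `list(from = c(row, col, slice), to = ...,
#'   radius, hu)` axis-aligned tube segments inside the lung region;
#'   `NULL` (default) draws two vessels scaled to the shape, `list()` none.
#' @param noise_sd additive Gaussian noise standard deviation (HU).
#' @param lung_semiaxes ellipse semi-axes (rows, cols) as voxel lengths;
#'   default 0.42 of each in-plane dimension.
#' @param seed integer seed for the noise.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(shape = c(64L, 64L, 3L),
                         background_hu = -850, tissue_hu = 40,
                         nodules = NULL, vessels = NULL,
                         noise_sd = 20, lung_semiaxes = NULL, seed = 1L) {
  if (length(shape) == 2L) shape <- c(shape, 1L)
  if (length(shape) != 3L || any(shape < 1))
    stop_param("shape must be (rows, cols, slices) with positive entries")
  if (is.null(lung_semiaxes)) lung_semiaxes <- 0.42 * shape[1:2]
  mid <- (shape[3L] + 1L) %/% 2L
  # structure defaults scale with the in-plane shape; at 64 x 64 x 3 they
  # give one radius-4 nodule at (20, 40, 2) and two radius-1.5 vessels
  if (is.null(nodules))
    nodules <- list(list(center = c(round(0.3125 * shape[1L]),
                                    round(0.625 * shape[2L]), mid),
                         radius = max(2, round(shape[1L] / 16)), hu = -50))
  if (is.null(vessels))
    vessels <- list(
      list(from = c(round(0.28125 * shape[1L]),
                    round(0.390625 * shape[2L]), mid),
           to = c(round(0.71875 * shape[1L]),
                  round(0.390625 * shape[2L]), mid),
           radius = 1.5, hu = 30),
      list(from = c(round(0.65625 * shape[1L]),
                    round(0.34375 * shape[2L]), mid),
           to = c(round(0.65625 * shape[1L]),
                  round(0.703125 * shape[2L]), mid),
           radius = 1.5, hu = 30))
  for (nd in nodules)
    if (is.null(nd$center) || is.null(nd$radius) || nd$radius < 1)
      stop_param("each nodule needs a center and a radius >= 1 voxel")
  for (vs in vessels) {
    if (is.null(vs$from) || is.null(vs$to) || is.null(vs$radius) ||
        vs$radius < 1)
      stop_param("each vessel needs from/to endpoints and a radius >= 1")
    if (sum(vs$from != vs$to) > 1L)
      stop_param("vessel segments must be axis-aligned")
  }
  if (!is_scalar_num(noise_sd) || noise_sd < 0)
    stop_param("noise_sd must be >= 0")
  structure(list(shape = as.integer(shape), background_hu = background_hu,
                 tissue_hu = tissue_hu, nodules = nodules, vessels = vessels,
                 noise_sd = noise_sd, lung_semiaxes = lung_semiaxes,
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

#' Generate a synthetic CT phantom
#'
#' Renders the piecewise-constant structures of a [phantom_spec()], adds
#' seeded Gaussian noise, and clips to the 12-bit HU range `[-1024, 3071]`.
#' The ground-truth mask is the union of the nodule spheres; the lung mask
#' is the elliptical lung region.  Identical specs produce identical
#' volumes, voxel for voxel.
#'
#' @param spec a [phantom_spec()].
#' @return a list with elements `volume` (a [ct_volume()] carrying the lung
#'   mask), `truth` (binary [nodule_mask()]), and `lung_mask` (logical
#'   array).
#' @examples
#' ph <- generate_phantom(phantom_spec(noise_sd = 0))
#' sort(unique(as.vector(ph$volume$voxels)))  # the four structure means
#' @export
generate_phantom <- function(spec = phantom_spec()) {
  stopifnot(inherits(spec, "phantom_spec"))
  d <- spec$shape
  ctr <- (d[1:2] + 1) / 2
  rows <- slice_coord(d, 1L); cols <- slice_coord(d, 2L)
  lung <- ((rows - ctr[1L]) / spec$lung_semiaxes[1L])^2 +
          ((cols - ctr[2L]) / spec$lung_semiaxes[2L])^2 <= 1

  vox <- array(spec$tissue_hu, d)
  vox[lung] <- spec$background_hu

  for (vs in spec$vessels) {
    tube <- segment_mask(d, vs$from, vs$to, vs$radius)
    if (any(tube & !lung))
      stop_param("vessel (%s)-(%s) extends outside the lung region",
                 paste(vs$from, collapse = ","),
                 paste(vs$to, collapse = ","))
    vox[tube] <- vs$hu
  }

  truth <- array(FALSE, d)
  for (nd in spec$nodules) {
    ball <- sphere_mask(d, nd$center, nd$radius)
    if (any(ball & !lung))
      stop_param("nodule at (%s) extends outside the lung region",
                 paste(nd$center, collapse = ","))
    vox[ball] <- nd$hu
    truth <- truth | ball
  }

  if (spec$noise_sd > 0)
    vox <- vox + with_seed(spec$seed,
                           array(stats::rnorm(length(vox), 0, spec$noise_sd),
                                 d))
  vox <- pmin(pmax(vox, -1024), 3071)

  list(volume = ct_volume(vox, lung_mask = lung),
       truth = nodule_mask(truth, "binary"),
       lung_mask = lung)
}

# Coordinate array along axis `ax` of a volume of dims d.
slice_coord <- function(d, ax) {
  perm <- array(0, d)
  idx <- slice.index(perm, ax)
  idx
}

sphere_mask <- function(d, center, radius) {
  r <- slice_coord(d, 1L); cc <- slice_coord(d, 2L); s <- slice_coord(d, 3L)
  (r - center[1L])^2 + (cc - center[2L])^2 + (s - center[3L])^2 <= radius^2
}

# Axis-aligned tube: voxels within `radius` (Euclidean) of the segment.
segment_mask <- function(d, from, to, radius) {
  r <- slice_coord(d, 1L); cc <- slice_coord(d, 2L); s <- slice_coord(d, 3L)
  lo <- pmin(from, to); hi <- pmax(from, to)
  # nearest point on the segment, coordinate-wise (segment is axis-aligned)
  nr <- pmin(pmax(r, lo[1L]), hi[1L])
  nc <- pmin(pmax(cc, lo[2L]), hi[2L])
  ns <- pmin(pmax(s, lo[3L]), hi[3L])
  (r - nr)^2 + (cc - nc)^2 + (s - ns)^2 <= radius^2
}

#' Emulated radiologist-consensus mask
#'
#' Builds a consensus-scored mask (0--1000) from a binary truth mask, for
#' exercising [consensus_filter()]: nodule interiors (surviving repeated
#' slice-wise 3x3 morphological erosion) score 1000, with each ring closer
#' to the boundary scoring `level_step` less, floored at `floor_score`.
#' This emulates the structure of agreement data -- radiologists concur on
#' nodule cores and diverge at the rim -- without claiming any particular
#' scoring formula.
#'
#' @param truth binary [nodule_mask()].
#' @param level_step score decrement per erosion ring.
#' @param floor_score minimum score of a truth voxel.
#' @return a consensus-semantics [nodule_mask()].  Thresholding at
#'   `1000 - level_step` recovers the once-less-than-maximally eroded core.
#' @export
generate_consensus <- function(truth, level_step = 200, floor_score = 100) {
  truth <- as_nodule_mask(truth)
  if (truth$semantics != "binary") stop_param("truth must be binary")
  g <- truth$grid
  depth <- array(NA_integer_, dim(g))
  cur <- g
  k <- 0L
  while (any(cur)) {
    depth[cur] <- k        # overwritten while the voxel keeps surviving
    cur <- erode_slicewise(cur)
    k <- k + 1L
  }
  dmax <- if (any(g)) max(depth[g]) else 0L
  score <- array(0, dim(g))
  score[g] <- pmax(1000 - level_step * (dmax - depth[g]), floor_score)
  nodule_mask(score, "consensus")
}

# Slice-wise 3x3 binary erosion (out-of-bounds treated as background).
erode_slicewise <- function(mask) {
  counts <- box_sum(mask + 0, 3L, 3L, 1L)
  mask & counts == 9
}

#' Salt-and-pepper corruption
#'
#' Replaces a random fraction of the eligible voxels with the extremes of
#' the 12-bit HU range (half -1024, half 3071), reproducibly from `seed`.
#' Used to probe the noise robustness of the spatial algorithms.
#'
#' @param volume a [ct_volume()].
#' @param fraction fraction of eligible voxels to corrupt.
#' @param seed integer seed.
#' @param low,high replacement intensities.
#' @return the corrupted [ct_volume()].
#' @export
add_salt_pepper <- function(volume, fraction = 0.05, seed = 1L,
                            low = -1024, high = 3071) {
  volume <- as_ct_volume(volume)
  if (!is_scalar_num(fraction) || fraction < 0 || fraction > 1)
    stop_param("fraction must lie in [0, 1]")
  idx <- eligible_index(volume)
  n <- round(fraction * length(idx))
  if (n > 0) {
    pick <- with_seed(seed, sample(idx, n))
    half <- seq_len(n) <= n / 2
    volume$voxels[pick[half]] <- low
    volume$voxels[pick[!half]] <- high
  }
  volume
}
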