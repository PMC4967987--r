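# Spatial (neighborhood) operations shared by SFCM, SKFCM, and MSKFCM.

# Scatter one membership row onto the volume grid (0 outside the eligible
# set), returning a full 3D array.
scatter_field <- function(values, voxel_index, dims) {
  a <- array(0, dims)
  a[voxel_index] <- values
  a
}

#' Spatial function: neighborhood membership sums
#'
#' For every voxel `j` and cluster `i`, `h[i, j]` is the sum of the
#' memberships to cluster `i` over the window centred on `j` (truncated at
#' the volume boundary, and restricted to lung-mask voxels when the volume
#' carries one).  The more neighbors favor cluster `i`, the larger `h[i, j]`.
#'
#' @param memberships a [membership_matrix()] whose `voxel_index` refers to
#'   `volume`.
#' @param volume the [ct_volume()] the memberships were computed on.
#' @param spec a [neighborhood_spec()].
#' @return numeric `c x n` matrix of neighborhood sums (class
#'   `spatial_function`), with the membership's `voxel_index` attribute.
#' @export
spatial_function <- function(memberships, volume, spec) {
  volume <- as_ct_volume(volume)
  stopifnot(inherits(spec, "neighborhood_spec"))
  idx <- attr(memberships, "voxel_index")
  if (is.null(idx)) idx <- seq_len(ncol(memberships))
  dims <- dim(volume$voxels)
  u <- unclass(memberships)
  h <- matrix(0, nrow(u), ncol(u))
  for (i in seq_len(nrow(u))) {
    field <- scatter_field(u[i, ], idx, dims)
    h[i, ] <- masked_box_sum(field, spec)[idx]
  }
  structure(h, voxel_index = as.integer(idx),
            class = c("spatial_function", "matrix", "array"))
}

#' Spatially weighted memberships
#'
#' `u'[i, j] = u[i, j]^p * h[i, j]^q / sum_k u[k, j]^p * h[k, j]^q`.
#' `p` weights the voxel's own (intensity-driven) membership, `q` the
#' neighborhood consensus; `p = 1, q = 0` returns the input unchanged.  A
#' voxel whose weights all vanish (possible when `p = 0` and it has no
#' eligible neighbors) falls back to its unweighted memberships, with a
#' warning.
#'
#' @param memberships `c x n` membership matrix.
#' @param h matching `c x n` [spatial_function()] values.
#' @param p,q non-negative weighting exponents.
#' @return a [membership_matrix()].
#' @examples
#' u <- membership_matrix(matrix(c(0.6, 0.4), 2))
#' h <- matrix(c(1, 3), 2)
#' spatial_memberships(u, h, 1, 1)  # (1/3, 2/3)
#' @export
spatial_memberships <- function(memberships, h, p, q) {
  if (!is_scalar_num(p) || !is_scalar_num(q) || p < 0 || q < 0)
    stop_param("p and q must be non-negative numbers")
  u <- unclass(memberships)
  hv <- unclass(h)
  if (!all(dim(u) == dim(hv)))
    stop_param("membership and spatial-function shapes differ")
  if (q == 0) {
    w <- u^p                # h^0 == 1 exactly, even where h == 0
  } else {
    w <- u^p * hv^q
  }
  cs <- colSums(w)
  bad <- cs == 0
  if (any(bad)) {
    warning(sprintf(paste0("%d voxel(s) had all-zero spatial weights; ",
                           "falling back to unweighted memberships there"),
                    sum(bad)))
    w[, bad] <- u[, bad, drop = FALSE]
    cs[bad] <- colSums(u[, bad, drop = FALSE])
  }
  out <- sweep(w, 2L, cs, "/")
  idx <- attr(memberships, "voxel_index")
  if (is.null(idx)) idx <- seq_len(ncol(u))
  as_membership(out, idx)
}

# Internal engine for the SKFCM penalty terms: per-cluster neighbor sums of
# an arbitrary per-voxel field g(x_r) over the (centre-excluded) window,
# together with per-voxel eligible-neighbor counts N_R.
skfcm_neighbor_sums <- function(fields, volume, spec) {
  dims <- dim(volume$voxels)
  elig <- eligible_array(volume)
  idx <- which(elig)
  nr <- masked_box_sum(elig + 0, spec)[idx]
  sums <- lapply(fields, function(f) {
    a <- array(0, dims)
    a[idx] <- f
    masked_box_sum(a, spec)[idx]
  })
  list(nr = nr, sums = sums, idx = idx)
}

#' SKFCM membership update
#'
#' Kernelized memberships with a spatial penalty: with
#' `B[i,k] = (1 - K(x_k, v_i)) + (alpha / N_R) * sum_{r in N_k} (1 - K(x_r, v_i))`,
#' `u[i,k] = B[i,k]^(-1/(m-1)) / sum_j B[j,k]^(-1/(m-1))`.  `N_k` is the
#' window around voxel `k` excluding the voxel itself and `N_R` its actual
#' (truncated, in-mask) cardinality; a voxel with no eligible neighbors drops
#' the penalty term.  A zero bracket for one or more clusters gives those
#' clusters a crisp equal split.
#'
#' @param intensities intensities of the eligible voxels, in the order of
#'   `which(volume$lung_mask)` (or all voxels when there is no mask).
#' @param centroids current centroids.
#' @param m fuzzifier > 1.
#' @param kernel a [kernel_spec()] (Gaussian; the SKFCM convention uses
#'   `variance_scale = "sigma2"`).
#' @param volume the [ct_volume()] providing the geometry.
#' @param spec penalty window, `include_center = FALSE`.
#' @param alpha penalty weight in `[0, 1)`; `alpha = 0` reduces exactly to
#'   [kfcm_memberships()].
#' @return a [membership_matrix()].
#' @export
skfcm_memberships <- function(intensities, centroids, m, kernel, volume,
                              spec, alpha) {
  check_fuzzifier(m)
  check_centroids(centroids)
  check_alpha(alpha)
  volume <- as_ct_volume(volume)
  if (spec$include_center)
    stop_param("the SKFCM penalty window must exclude the centre voxel")
  b0 <- 1 - kernel_matrix(intensities, centroids, kernel)
  b0[b0 < 0] <- 0
  ns <- skfcm_neighbor_sums(split_rows(b0), volume, spec)
  nr <- pmax(ns$nr, 1)  # isolated voxels: penalty contributes 0 anyway
  b <- b0
  for (i in seq_along(centroids))
    b[i, ] <- b0[i, ] + (alpha / nr) * ns$sums[[i]]
  w <- b^(-1 / (m - 1))
  u <- normalize_memberships(w, b == 0)
  as_membership(u, ns$idx)
}

#' SKFCM centroid update
#'
#' `v_i = sum_k u^m (K(x_k,v_i) x_k + (alpha/N_R) sum_r K(x_r,v_i) x_r) /
#'        sum_k u^m (K(x_k,v_i)     + (alpha/N_R) sum_r K(x_r,v_i))`,
#' with the kernel evaluated against the previous centroids.
#'
#' @inheritParams skfcm_memberships
#' @param centroids_prev previous iteration's centroids.
#' @param memberships current `c x n` memberships.
#' @return numeric vector of updated centroids.
#' @export
skfcm_centroids <- function(intensities, centroids_prev, memberships, m,
                            kernel, volume, spec, alpha) {
  check_fuzzifier(m)
  check_alpha(alpha)
  volume <- as_ct_volume(volume)
  if (spec$include_center)
    stop_param("the SKFCM penalty window must exclude the centre voxel")
  k <- kernel_matrix(intensities, centroids_prev, kernel)
  kx <- sweep(k, 2L, intensities, "*")
  ns <- skfcm_neighbor_sums(c(split_rows(k), split_rows(kx)), volume, spec)
  nr <- pmax(ns$nr, 1)
  cc <- length(centroids_prev)
  um <- unclass(memberships)^m
  v <- numeric(cc)
  for (i in seq_len(cc)) {
    num <- sum(um[i, ] * (kx[i, ] + (alpha / nr) * ns$sums[[cc + i]]))
    den <- sum(um[i, ] * (k[i, ] + (alpha / nr) * ns$sums[[i]]))
    if (den <= .Machine$double.xmin)
      stop(sprintf("internal error: vanishing SKFCM denominator, cluster %d",
                   i))
    v[i] <- num / den
  }
  v
}

split_rows <- function(m) lapply(seq_len(nrow(m)), function(i) m[i, ])

check_alpha <- function(alpha) {
  if (!is_scalar_num(alpha) || alpha < 0 || alpha >= 1)
    stop_param("alpha must lie in [0, 1) (got %s)", format(alpha))
}
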