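#' Fuzzy membership matrix
#'
#' A `c x n` matrix of memberships `u[i, k]` of voxel `k` to cluster `i`:
#' entries lie in `[0, 1]` and every column sums to 1 (within 1e-9).  The
#' `"voxel_index"` attribute maps column `k` to the linear index of the voxel
#' in its volume array, so spatial operations can place memberships back on
#' the grid.
#'
#' @param values numeric `c x n` matrix.
#' @param voxel_index integer vector of length `n` of linear voxel indices.
#' @return `values` with class `membership_matrix` and the index attribute.
#' @export
membership_matrix <- function(values, voxel_index = seq_len(ncol(values))) {
  if (!is.matrix(values) || !is.numeric(values))
    stop_param("memberships must be a numeric matrix (clusters x voxels)")
  if (length(voxel_index) != ncol(values))
    stop_param("voxel_index length %d != number of voxels %d",
               length(voxel_index), ncol(values))
  if (any(values < -1e-9) || any(values > 1 + 1e-9))
    stop_param("memberships must lie in [0, 1]")
  cs <- colSums(values)
  if (any(abs(cs - 1) > 1e-9))
    stop_param("membership columns must sum to 1 (max deviation %.3g)",
               max(abs(cs - 1)))
  structure(values, voxel_index = as.integer(voxel_index),
            class = c("membership_matrix", class(values)))
}

as_membership <- function(values, voxel_index) {
  structure(values, voxel_index = as.integer(voxel_index),
            class = c("membership_matrix", "matrix", "array"))
}

#' @export
print.membership_matrix <- function(x, ...) {
  cat(sprintf("membership_matrix: %d clusters x %d voxels\n",
              nrow(x), ncol(x)))
  if (ncol(x) <= 10L) print(unclass(x)[, , drop = FALSE], ...)
  else print(unclass(x)[, 1:10, drop = FALSE], ...)
  invisible(x)
}

# Normalize a c x n matrix of non-negative column scores into memberships,
# treating columns flagged in `crisp` (logical c x n, typically score == 0 on
# an inverse-distance scale) by an equal split over the flagged clusters.
normalize_memberships <- function(w, crisp) {
  n <- ncol(w)
  u <- sweep(w, 2L, colSums(w), "/")
  hit <- colSums(crisp) > 0L
  if (any(hit)) {
    cz <- crisp[, hit, drop = FALSE]
    u[, hit] <- sweep(cz, 2L, colSums(cz), "/")
  }
  u
}

#' FCM membership update
#'
#' The standard fuzzy c-means membership: with distances
#' `d[i,k] = |x_k - v_i|`,
#' `u[i,k] = 1 / sum_j (d[i,k] / d[j,k])^(2/(m-1))`.
#' When a voxel coincides with one or more centroids, membership 1 is split
#' equally among the coinciding clusters (the usual singularity convention).
#'
#' @param intensities numeric vector of voxel intensities (HU).
#' @param centroids numeric vector of pairwise-distinct cluster centroids.
#' @param m fuzzifier, > 1.
#' @param voxel_index optional voxel index carried onto the result.
#' @return a [membership_matrix()].
#' @examples
#' fcm_memberships(1, c(0, 3), m = 2)  # (0.8, 0.2)
#' @export
fcm_memberships <- function(intensities, centroids, m,
                            voxel_index = seq_along(intensities)) {
  check_fuzzifier(m)
  check_centroids(centroids)
  d2 <- outer(centroids, intensities, function(v, x) (x - v)^2)
  w <- d2^(-1 / (m - 1))        # (d^2)^{-1/(m-1)} = d^{-2/(m-1)}
  u <- normalize_memberships(w, d2 == 0)
  as_membership(u, voxel_index)
}

#' FCM centroid update
#'
#' `v_i = sum_k u[i,k]^m x_k / sum_k u[i,k]^m`; each centroid lies within the
#' data's intensity range.
#'
#' @inheritParams fcm_memberships
#' @param memberships a `c x n` membership matrix.
#' @return numeric vector of `c` centroids.
#' @export
fcm_centroids <- function(intensities, memberships, m) {
  check_fuzzifier(m)
  um <- unclass(memberships)^m
  den <- rowSums(um)
  if (any(den <= 0))
    stop("internal error: all-zero membership weight for a cluster")
  as.numeric(um %*% intensities) / den
}

#' Kernelized membership update (KFCM / MSKFCM)
#'
#' With kernel distance `1 - K(x_k, v_i)`,
#' `u[i,k] = (1 - K)^(-1/(m-1)) / sum_j (1 - K_j)^(-1/(m-1))`.
#' A voxel coinciding with a centroid (`1 - K = 0`) gets crisp membership,
#' split equally if several centroids coincide.
#'
#' @inheritParams fcm_memberships
#' @param kernel a [kernel_spec()].
#' @return a [membership_matrix()].
#' @export
kfcm_memberships <- function(intensities, centroids, m, kernel,
                             voxel_index = seq_along(intensities)) {
  check_fuzzifier(m)
  check_centroids(centroids)
  b <- 1 - kernel_matrix(intensities, centroids, kernel)
  b[b < 0] <- 0   # polynomial kernels can exceed 1; clamp distance at 0
  w <- b^(-1 / (m - 1))
  u <- normalize_memberships(w, b == 0)
  as_membership(u, voxel_index)
}

#' Kernelized centroid update (KFCM)
#'
#' `v_i = sum_k u^m K(x_k, v_i) x_k / sum_k u^m K(x_k, v_i)`, with the kernel
#' evaluated against the previous iteration's centroids.
#'
#' @inheritParams kfcm_memberships
#' @param centroids_prev centroids from the previous iteration.
#' @param memberships `c x n` membership matrix.
#' @return numeric vector of `c` updated centroids.
#' @export
kfcm_centroids <- function(intensities, centroids_prev, memberships, m,
                           kernel) {
  check_fuzzifier(m)
  k <- kernel_matrix(intensities, centroids_prev, kernel)
  w <- unclass(memberships)^m * k
  den <- rowSums(w)
  if (any(den <= .Machine$double.xmin))
    stop(sprintf(paste0("internal error: vanishing centroid denominator for",
                        " cluster(s) %s (kernel weights collapsed to 0)"),
                 paste(which(den <= .Machine$double.xmin), collapse = ", ")))
  as.numeric(w %*% intensities) / den
}

#' Crisp labels from fuzzy memberships
#'
#' Assigns every voxel the cluster of maximal membership; ties break to the
#' lowest cluster index.
#'
#' @param x a membership matrix (or a fitted [fuzzy_cluster()] object).
#' @param ... unused.
#' @return for a membership matrix, an integer vector of cluster labels
#'   (1-based) per column; for a fit, a labeled array (see the method).
#' @examples
#' m <- membership_matrix(matrix(c(0.7, 0.3, 0.5, 0.5), 2))
#' defuzzify(m)  # 1, 1
#' @export
defuzzify <- function(x, ...) UseMethod("defuzzify")

#' @export
defuzzify.default <- function(x, ...) {
  x <- unclass(x)
  if (!is.matrix(x)) stop_param("defuzzify needs a membership matrix")
  max.col(t(x), ties.method = "first")
}

#' @export
defuzzify.membership_matrix <- function(x, ...) defuzzify.default(x, ...)

check_fuzzifier <- function(m) {
  if (!is_scalar_num(m) || m <= 1)
    stop_param("the fuzzifier m must be a number > 1 (got %s)", format(m))
}

check_centroids <- function(v) {
  if (!is.numeric(v) || length(v) < 1L || !all(is.finite(v)))
    stop_param("centroids must be finite numbers")
  if (anyDuplicated(v))
    stop_param("centroids must be pairwise distinct")
}
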