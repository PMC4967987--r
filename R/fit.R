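#' Centroid initialization specification
#'
#' Two initialization modes, mirroring how the operator would seed the
#' clustering of a CT slice:
#' * `"samples"`: the operator supplies at least one sample intensity (or
#'   voxel coordinate) per cluster; each initial centroid is the mean of its
#'   cluster's samples.
#' * `"random"`: `c` pairwise-distinct intensities drawn uniformly and
#'   reproducibly (from `seed`) over the eligible intensity range.
#'
#' @param mode `"random"` or `"samples"`.
#' @param samples for `"samples"` mode: a list with one element per cluster,
#'   each either a numeric vector of intensities or an integer matrix of
#'   `(row, col, slice)` coordinates (looked up in the volume).
#' @param seed integer seed for `"random"` mode.
#' @return An object of class `init_spec`.
#' @export
init_spec <- function(mode = c("random", "samples"), samples = NULL,
                      seed = 1L) {
  mode <- match.arg(mode)
  if (mode == "samples") {
    if (!is.list(samples) || length(samples) < 1L)
      stop_param("samples mode needs a list with one element per cluster")
    empty <- vapply(samples, function(s) length(s) < 1L, logical(1))
    if (any(empty))
      stop_param("cluster(s) %s have no samples",
                 paste(which(empty), collapse = ", "))
  }
  if (!is_count(seed)) stop_param("seed must be a single integer")
  structure(list(mode = mode, samples = samples, seed = as.integer(seed)),
            class = "init_spec")
}

#' Initial centroids
#'
#' @param volume a [ct_volume()].
#' @param clusters number of clusters `c >= 1`.
#' @param init an [init_spec()].
#' @return numeric vector of `clusters` pairwise-distinct centroids
#'   (duplicates perturbed by the smallest representable step).
#' @export
init_centroids <- function(volume, clusters, init = init_spec()) {
  volume <- as_ct_volume(volume)
  stopifnot(inherits(init, "init_spec"))
  if (!is_count(clusters) || clusters < 1L)
    stop_param("clusters must be an integer >= 1")
  x <- volume$voxels[eligible_index(volume)]
  if (init$mode == "samples") {
    if (length(init$samples) != clusters)
      stop_param("%d clusters but %d sample sets", clusters,
                 length(init$samples))
    v <- vapply(init$samples, function(s) {
      if (is.matrix(s)) {
        ii <- apply(s, 1L, function(co)
          volume$voxels[co[1L], co[2L], co[3L]])
        mean(ii)
      } else mean(as.numeric(s))
    }, numeric(1))
  } else {
    rng <- range(x)
    v <- with_seed(init$seed, stats::runif(clusters, rng[1L], rng[2L]))
  }
  make_distinct(v)
}

# --- parameter bundle ------------------------------------------------------

validate_params <- function(clusters, fuzzifier, epsilon, max_iter, p, q,
                            alpha) {
  if (!is_count(clusters) || clusters < 1L)
    stop_param("clusters must be an integer >= 1")
  check_fuzzifier(fuzzifier)
  if (!is_scalar_num(epsilon) || epsilon <= 0)
    stop_param("epsilon must be > 0")
  if (!is_count(max_iter) || max_iter < 1L)
    stop_param("max_iter must be an integer >= 1")
  if (!is_scalar_num(p) || !is_scalar_num(q) || p < 0 || q < 0)
    stop_param("p and q must be non-negative")
  check_alpha(alpha)
}

# --- single-volume driver --------------------------------------------------

# One joint fit over the eligible voxels of `volume`.  Returns centroids,
# final memberships (and the memberships used for labeling), traces.
fit_engine <- function(volume, algorithm, v0, clusters, m, epsilon, max_iter,
                       kernel, nb, p, q, alpha) {
  idx <- eligible_index(volume)
  x <- volume$voxels[idx]

  memb_step <- switch(algorithm,
    fcm = function(v) fcm_memberships(x, v, m, idx),
    kfcm = ,
    mskfcm = function(v) kfcm_memberships(x, v, m, kernel, idx),
    sfcm = function(v) fcm_memberships(x, v, m, idx),
    skfcm = function(v) skfcm_memberships(x, v, m, kernel, volume, nb, alpha)
  )
  # spatial reweighting (identity for fcm/kfcm/skfcm)
  weight_step <- switch(algorithm,
    sfcm = ,
    mskfcm = function(u) {
      h <- spatial_function(u, volume, nb)
      spatial_memberships(u, h, p, q)
    },
    function(u) u
  )
  cent_step <- switch(algorithm,
    fcm = ,
    sfcm = function(v, u) fcm_centroids(x, u, m),
    kfcm = ,
    mskfcm = function(v, u) kfcm_centroids(x, v, u, m, kernel),
    skfcm = function(v, u) skfcm_centroids(x, v, u, m, kernel, volume, nb,
                                           alpha)
  )
  objective <- switch(algorithm,
    fcm = ,
    sfcm = function(u, v) {
      d2 <- outer(v, x, function(vi, xx) (xx - vi)^2)
      sum(unclass(u)^m * d2)
    },
    kfcm = ,
    mskfcm = function(u, v)
      sum(unclass(u)^m * (1 - kernel_matrix(x, v, kernel))),
    skfcm = function(u, v) {
      b0 <- 1 - kernel_matrix(x, v, kernel)
      ns <- skfcm_neighbor_sums(split_rows(b0), volume, nb)
      nr <- pmax(ns$nr, 1)
      pen <- do.call(rbind, ns$sums)
      sum(unclass(u)^m * b0) +
        sum(sweep(unclass(u)^m * pen, 2L, alpha / nr, "*"))
    }
  )

  v <- v0
  obj <- numeric(0)
  vtrace <- matrix(v, nrow = 1L)
  delta <- numeric(0)
  converged <- FALSE
  iterations <- 0L
  for (it in seq_len(max_iter)) {
    u_raw <- memb_step(v)
    u <- weight_step(u_raw)
    v_new <- cent_step(v, u)
    v_new <- make_distinct(v_new)
    d <- max(abs(v_new - v))
    obj <- c(obj, objective(u, v_new))
    vtrace <- rbind(vtrace, v_new)
    delta <- c(delta, d)
    v <- v_new
    iterations <- it
    if (d <= epsilon) { converged <- TRUE; break }
  }
  # fixed-point consistency: final memberships recomputed from the final
  # centroids (for spatial algorithms the full chain, so labels come from
  # the spatially weighted memberships)
  u_final <- weight_step(memb_step(v))
  list(centroids = v, memberships = u_final, iterations = iterations,
       converged = converged, objective_trace = obj,
       centroid_trace = vtrace, delta_trace = delta, voxel_index = idx,
       n = length(x))
}

#' Fit a fuzzy clustering segmentation model
#'
#' Partitions the (lung-masked) voxels of a CT volume into `clusters` fuzzy
#' clusters of similar attenuation, using one of five related algorithms:
#'
#' * `"fcm"`   -- classical fuzzy c-means on voxel intensity.
#' * `"kfcm"`  -- kernelized FCM: Euclidean distance replaced by a kernel
#'   distance `1 - K(x, v)` (Gaussian by default), emulating clustering in a
#'   higher-dimensional feature space.
#' * `"sfcm"`  -- spatial FCM: each iteration reweights the FCM memberships
#'   by the neighborhood consensus `h` via `u^p * h^q`, favoring locally
#'   coherent labels.
#' * `"skfcm"` -- kernelized FCM with a spatial penalty term of weight
#'   `alpha` summing the kernel distances of each voxel's neighbors
#'   (centre excluded).
#' * `"mskfcm"` -- the combination of KFCM and SFCM: kernelized memberships,
#'   then the `u^p * h^q` spatial reweighting, then kernel-weighted
#'   centroids.
#'
#' Iteration alternates membership and centroid updates until the maximum
#' absolute centroid change drops to `epsilon` or `max_iter` is reached
#' (non-convergence is reported, not an error).  With a 2D window mode on a
#' multi-slice volume each slice is fit independently (the per-slice
#' protocol of thoracic CT reading); a 3D window fits the volume jointly
#' with rectangular-prism neighborhoods spanning adjacent slices.
#'
#' @param volume a [ct_volume()] (or matrix/array coercible to one).
#' @param algorithm one of `"fcm"`, `"kfcm"`, `"sfcm"`, `"skfcm"`,
#'   `"mskfcm"`.
#' @param clusters number of clusters; 3 works best for nodule ROI detection
#'   in lung CT.
#' @param fuzzifier fuzzifier `m > 1` (default 2).
#' @param epsilon convergence threshold on the max-norm centroid change, HU.
#' @param max_iter iteration cap.
#' @param kernel a [kernel_spec()]; defaults to a Gaussian with
#'   `sigma = 300` HU, denominator `2*sigma^2` for kfcm/mskfcm and `sigma^2`
#'   for skfcm.
#' @param neighborhood a [neighborhood_spec()]; defaults to a 2D 3x3 window
#'   (centre included for sfcm/mskfcm, excluded for the skfcm penalty).
#' @param p,q spatial weighting exponents (sfcm, mskfcm).
#' @param alpha spatial penalty weight in `[0, 1)` (skfcm).
#' @param init an [init_spec()].
#' @param slice_wise fit each slice independently?  Default: `TRUE` when the
#'   window mode is 2D and the volume has more than one slice.
#' @return An object of class `fuzzy_fit`; see Details.  Key elements:
#'   `centroids` (`c x`number-of-fits matrix), `memberships` (a
#'   [membership_matrix()] over all eligible voxels), `fits` (per-fit
#'   iteration diagnostics), `converged`, `iterations`.
#' @examples
#' ph <- generate_phantom(phantom_spec(shape = c(32, 32, 1), noise_sd = 10))
#' fit <- fuzzy_cluster(ph$volume, "fcm", clusters = 3,
#'                      init = init_spec("samples",
#'                        samples = list(-850, -50, 40)))
#' coef(fit)
#' @export
fuzzy_cluster <- function(volume,
                          algorithm = c("fcm", "kfcm", "sfcm", "skfcm",
                                        "mskfcm"),
                          clusters = 3, fuzzifier = 2, epsilon = 1e-3,
                          max_iter = 200, kernel = NULL, neighborhood = NULL,
                          p = 1, q = 1, alpha = 0.1, init = init_spec(),
                          slice_wise = NULL) {
  algorithm <- match.arg(algorithm)
  volume <- as_ct_volume(volume)
  validate_params(clusters, fuzzifier, epsilon, max_iter, p, q, alpha)

  if (is.null(kernel))
    kernel <- kernel_spec("gaussian", sigma = 300,
                          variance_scale = if (algorithm == "skfcm")
                            "sigma2" else "2sigma2")
  if (is.null(neighborhood))
    neighborhood <- neighborhood_spec("2d", 3L,
                                      include_center = algorithm != "skfcm")
  if (algorithm == "skfcm" && neighborhood$include_center)
    stop_param("skfcm's penalty window excludes the centre voxel; use
  neighborhood_spec(..., include_center = FALSE)")

  d <- dim(volume$voxels)
  if (is.null(slice_wise))
    slice_wise <- neighborhood$mode == "2d" && d[3L] > 1L
  if (slice_wise && neighborhood$mode == "3d")
    stop_param("slice_wise fitting is incompatible with a 3D window")

  v0 <- init_centroids(volume, clusters, init)

  run_one <- function(vol)
    fit_engine(vol, algorithm, v0, clusters, fuzzifier, epsilon, max_iter,
               kernel, neighborhood, p, q, alpha)

  if (slice_wise) {
    fits <- lapply(seq_len(d[3L]), function(s) {
      sub <- volume_slice(volume, s)
      r <- run_one(sub)
      # remap depth-1 linear indices to the parent volume
      r$voxel_index <- r$voxel_index + (s - 1L) * d[1L] * d[2L]
      r$slice <- s
      r
    })
  } else {
    fits <- list(run_one(volume))
  }

  u_all <- do.call(cbind, lapply(fits, function(f) unclass(f$memberships)))
  idx_all <- unlist(lapply(fits, `[[`, "voxel_index"))
  memberships <- as_membership(u_all, idx_all)
  centroids <- vapply(fits, `[[`, numeric(clusters), "centroids")
  centroids <- matrix(centroids, nrow = clusters)

  structure(list(
    algorithm = algorithm,
    centroids = centroids,
    memberships = memberships,
    fits = fits,
    slice_wise = slice_wise,
    iterations = vapply(fits, `[[`, integer(1), "iterations"),
    converged = all(vapply(fits, `[[`, logical(1), "converged")),
    params = list(clusters = as.integer(clusters), fuzzifier = fuzzifier,
                  epsilon = epsilon, max_iter = as.integer(max_iter),
                  kernel = kernel, neighborhood = neighborhood,
                  p = p, q = q, alpha = alpha, init = init),
    volume = volume,
    call = match.call()
  ), class = "fuzzy_fit")
}

#' Pick the cluster that represents the nodule
#'
#' With a `hint` (sample nodule intensities) the cluster whose centroid is
#' nearest the mean hint is chosen.  Without a hint and exactly 3 clusters,
#' the midrange cluster (middle centroid after sorting) is chosen: candidate
#' nodules have attenuation between air-filled parenchyma and chest-wall
#' tissue.  Any other clusterless-hint configuration is an error.
#'
#' @param fit a [fuzzy_cluster()] fit.
#' @param hint optional numeric vector of nodule sample intensities (HU).
#' @return integer vector of selected cluster indices, one per slice fit
#'   (length 1 for a joint fit).
#' @export
select_nodule_cluster <- function(fit, hint = NULL) {
  stopifnot(inherits(fit, "fuzzy_fit"))
  cc <- nrow(fit$centroids)
  apply(fit$centroids, 2L, function(v) {
    if (!is.null(hint)) {
      which.min(abs(v - mean(hint)))
    } else if (cc == 3L) {
      order(v)[2L]
    } else {
      stop_param(paste0("cannot auto-select the nodule cluster with c = %d;",
                        " supply `hint` intensities"), cc)
    }
  })
}

#' Binary candidate-nodule mask from a fit
#'
#' Defuzzifies the fit and marks the voxels labeled with the selected
#' cluster (per slice fit when the model was fit slice-wise).
#'
#' @param fit a [fuzzy_cluster()] fit.
#' @param cluster integer cluster selection, one per slice fit; defaults to
#'   [select_nodule_cluster()].
#' @param hint passed to [select_nodule_cluster()] when `cluster` is `NULL`.
#' @return a binary [nodule_mask()] aligned with the fitted volume.
#' @export
roi_mask <- function(fit, cluster = NULL, hint = NULL) {
  stopifnot(inherits(fit, "fuzzy_fit"))
  if (is.null(cluster)) cluster <- select_nodule_cluster(fit, hint)
  if (length(cluster) == 1L) cluster <- rep(cluster, length(fit$fits))
  dims <- dim(fit$volume$voxels)
  grid <- array(FALSE, dims)
  for (j in seq_along(fit$fits)) {
    f <- fit$fits[[j]]
    lab <- defuzzify(f$memberships)
    grid[f$voxel_index[lab == cluster[j]]] <- TRUE
  }
  nodule_mask(grid, semantics = "binary")
}
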