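test_that("spatial function trivial cases: uniform and crisp windows", {
  vol <- ct_volume(array(0, c(5, 5, 1)))
  # uniform memberships 1/c: interior h = 9/c for a 3x3 window with centre
  u <- as_mm(matrix(1 / 3, 3, 25))
  h <- spatial_function(u, vol, neighborhood_spec("2d", 3))
  expect_equal(h[, 13], rep(3, 3))  # 9/3 per cluster at the centre voxel
  # per-voxel cluster sums equal the in-window neighbor count
  counts <- colSums(unclass(h))
  corner_cols <- c(1, 5, 21, 25)
  expect_equal(counts[corner_cols], rep(4, 4))
  expect_equal(counts[13], 9)
  # crisp all-cluster-0 window
  uc <- as_mm(rbind(rep(1, 25), rep(0, 25)))
  hc <- spatial_function(uc, vol, neighborhood_spec("2d", 3))
  expect_equal(hc[1, 13], 9)
  expect_equal(hc[2, ], rep(0, 25))
})

test_that("spatial function equals the brute-force double loop", {
  for (seed in 1:3) {
    vol <- random_volume(c(5, 5, 3), seed, masked = seed == 3)
    idx <- which(if (is.null(vol$lung_mask)) array(TRUE, dim(vol$voxels))
                 else vol$lung_mask)
    set.seed(seed + 100)
    u <- random_memberships(3, length(idx))
    for (spec in list(neighborhood_spec("2d", 3),
                      neighborhood_spec("3d", 3),
                      neighborhood_spec("2d", 3, include_center = FALSE))) {
      got <- spatial_function(as_mm(u, idx), vol, spec)
      want <- o_spatial_h(u, idx, dim(vol$voxels), spec$size,
                          if (spec$mode == "3d") spec$depth else 1L,
                          spec$include_center)
      expect_equal(unclass(got), want, tolerance = 1e-9,
                   ignore_attr = TRUE)
    }
  }
})

test_that("spatial membership weighting matches hand values and reductions", {
  u <- as_mm(matrix(c(0.6, 0.4), 2))
  h <- matrix(c(1, 3), 2)
  expect_equal(as.numeric(spatial_memberships(u, h, 1, 1)), c(1 / 3, 2 / 3),
               tolerance = 1e-12)
  # p = 1, q = 0 is the identity
  set.seed(5)
  u2 <- as_mm(random_memberships(3, 40))
  expect_equal(unclass(spatial_memberships(u2, matrix(0, 3, 40), 1, 0)),
               unclass(u2), tolerance = 1e-12, ignore_attr = TRUE)
  # p = 0, q = 1 is the pure spatial share
  h2 <- matrix(runif(120, 0.1, 5), 3, 40)
  got <- spatial_memberships(u2, h2, 0, 1)
  expect_equal(unclass(got), sweep(h2, 2, colSums(h2), "/"),
               tolerance = 1e-12, ignore_attr = TRUE)
  # random case vs oracle
  got3 <- spatial_memberships(u2, h2, 1.3, 0.7)
  expect_equal(unclass(got3), o_spatial_u(unclass(u2), h2, 1.3, 0.7),
               tolerance = 1e-9, ignore_attr = TRUE)
  expect_valid_memberships(got3)
})

test_that("all-zero spatial weights fall back to the unweighted memberships", {
  u <- as_mm(matrix(c(0.6, 0.4, 0.5, 0.5), 2))
  h <- matrix(c(0, 0, 1, 1), 2)
  expect_warning(got <- spatial_memberships(u, h, 0, 1), "all-zero")
  expect_equal(got[, 1], c(0.6, 0.4))
  expect_equal(got[, 2], c(0.5, 0.5))
})

test_that("SKFCM updates match the scalar-loop oracle, incl. masked volumes", {
  for (seed in 1:3) {
    masked <- seed == 3
    vol <- random_volume(c(4, 4, 2), seed + 20, masked = masked)
    idx <- which(if (is.null(vol$lung_mask)) array(TRUE, dim(vol$voxels))
                 else vol$lung_mask)
    x <- vol$voxels[idx]
    v <- c(-700, -200, 50)
    m <- 2; sig <- 300; alpha <- 0.15
    k <- kernel_spec("gaussian", sigma = sig, variance_scale = "sigma2")
    for (spec in list(
      neighborhood_spec("2d", 3, include_center = FALSE),
      neighborhood_spec("3d", 3, include_center = FALSE))) {
      dep <- if (spec$mode == "3d") spec$depth else 1L
      u <- skfcm_memberships(x, v, m, k, vol, spec, alpha)
      want_u <- o_skfcm_u(x, v, m, sig, idx, dim(vol$voxels), spec$size,
                          dep, alpha)
      expect_equal(unclass(u), want_u, tolerance = 1e-9, ignore_attr = TRUE)
      expect_valid_memberships(u)
      v2 <- skfcm_centroids(x, v, u, m, k, vol, spec, alpha)
      want_v <- o_skfcm_v(x, v, unclass(u), m, sig, idx, dim(vol$voxels),
                          spec$size, dep, alpha)
      expect_equal(v2, want_v, tolerance = 1e-9)
      expect_true(all(v2 >= min(x) & v2 <= max(x)))
    }
  }
})

test_that("SKFCM hand case on a 3-voxel slice", {
  # 1x3 image, window 3x3 (truncated to in-line neighbors), c = 2
  vol <- ct_volume(matrix(c(0, 10, 100), 1, 3))
  x <- c(0, 10, 100)
  v <- c(5, 90); m <- 2; alpha <- 0.1; sig <- 50
  k <- kernel_spec("gaussian", sigma = sig, variance_scale = "sigma2")
  spec <- neighborhood_spec("2d", 3, include_center = FALSE)
  g <- function(a, b) exp(-(a - b)^2 / sig^2)
  # voxel 2 has neighbors {1, 3}; voxels 1 and 3 have single neighbor {2}
  b_hand <- function(xk, nbr, vi) {
    (1 - g(xk, vi)) + alpha / length(nbr) * sum(1 - g(nbr, vi))
  }
  b11 <- b_hand(0, 10, 5);  b21 <- b_hand(0, 10, 90)
  u1 <- (1 / b11) / (1 / b11 + 1 / b21)
  u <- skfcm_memberships(x, v, m, k, vol, spec, alpha)
  expect_equal(u[1, 1], u1, tolerance = 1e-12)
})

test_that("SKFCM with alpha = 0 reduces exactly to KFCM", {
  vol <- random_volume(c(6, 6, 1), 9)
  x <- as.numeric(vol$voxels)
  v <- c(-800, -300, 0)
  k <- kernel_spec("gaussian", sigma = 250, variance_scale = "sigma2")
  spec <- neighborhood_spec("2d", 3, include_center = FALSE)
  u_sk <- skfcm_memberships(x, v, 2, k, vol, spec, alpha = 0)
  u_k <- kfcm_memberships(x, v, 2, k)
  expect_equal(unclass(u_sk), unclass(u_k), tolerance = 1e-9,
               ignore_attr = TRUE)
  v_sk <- skfcm_centroids(x, v, u_k, 2, k, vol, spec, alpha = 0)
  v_k <- kfcm_centroids(x, v, u_k, 2, k)
  expect_equal(v_sk, v_k, tolerance = 1e-9)
})

test_that("the SKFCM penalty window must exclude the centre", {
  vol <- random_volume(c(4, 4, 1), 2)
  x <- as.numeric(vol$voxels)
  k <- kernel_spec("gaussian", sigma = 250, variance_scale = "sigma2")
  expect_error(
    skfcm_memberships(x, c(-500, 0), 2, k, vol, neighborhood_spec("2d", 3),
                      0.1),
    "exclude")
})
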