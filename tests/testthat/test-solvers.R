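# Two-population test image: air-like and nodule-like intensities.
two_pop_volume <- function(n_side = 32, seed = 3, means = c(-850, -50),
                           sd = 20) {
  set.seed(seed)
  n <- n_side^2
  x <- c(rnorm(n / 2, means[1], sd), rnorm(n / 2, means[2], sd))
  ct_volume(matrix(sample(x), n_side, n_side))
}

test_that("operator and random initialization behave as specified", {
  vol <- ct_volume(matrix(c(-800, -820, 10, 30), 2, 2))
  v <- init_centroids(vol, 2, init_spec("samples",
                                        samples = list(c(-800, -820),
                                                       c(10, 30))))
  expect_equal(v, c(-810, 20))
  # coordinate samples are looked up in the volume
  v2 <- init_centroids(vol, 1,
                       init_spec("samples",
                                 samples = list(rbind(c(1, 1, 1),
                                                      c(2, 1, 1)))))
  expect_equal(v2, -810)
  # random mode is reproducible and in-range
  vol2 <- two_pop_volume()
  a <- init_centroids(vol2, 3, init_spec("random", seed = 11))
  b <- init_centroids(vol2, 3, init_spec("random", seed = 11))
  expect_identical(a, b)
  expect_true(all(a >= min(vol2$voxels) & a <= max(vol2$voxels)))
  expect_false(anyDuplicated(a) > 0)
  # degenerate constant image with c = 1
  expect_equal(init_centroids(ct_volume(matrix(50, 3, 3)), 1,
                              init_spec("samples", samples = list(50))), 50)
  expect_error(init_spec("samples", samples = list(numeric(0), 1)),
               "no samples")
})

test_that("FCM converges on a constant image in one iteration", {
  for (alg in c("fcm", "kfcm", "sfcm", "skfcm", "mskfcm")) {
    fit <- fuzzy_cluster(ct_volume(matrix(50, 4, 4)), alg, clusters = 1,
                         init = init_spec("samples", samples = list(50)))
    expect_equal(fit$iterations, 1L)
    expect_true(fit$converged)
    expect_equal(as.numeric(fit$centroids), 50)
  }
})

test_that("FCM and KFCM recover two well-separated population means", {
  vol <- two_pop_volume(32, seed = 3)
  init <- init_spec("samples", samples = list(-850, -50))
  for (alg in c("fcm", "kfcm")) {
    fit <- fuzzy_cluster(vol, alg, clusters = 2, init = init)
    expect_true(fit$converged)
    v <- sort(as.numeric(fit$centroids))
    expect_lt(abs(v[1] - -850), 10)
    expect_lt(abs(v[2] - -50), 10)
  }
})

test_that("the FCM objective trace is non-increasing", {
  vol <- two_pop_volume(16, seed = 8)
  fit <- fuzzy_cluster(vol, "fcm", clusters = 3,
                       init = init_spec("random", seed = 2))
  tr <- fit$fits[[1]]$objective_trace
  expect_gte(length(tr), 2)
  expect_true(all(diff(tr) <= 1e-6 * abs(tr[-length(tr)])))
})

test_that("final memberships are the fixed point of the final centroids", {
  vol <- two_pop_volume(16, seed = 5)
  fit <- fuzzy_cluster(vol, "fcm", clusters = 2,
                       init = init_spec("samples", samples = list(-850, -50)))
  x <- as.numeric(vol$voxels)
  want <- fcm_memberships(x, as.numeric(fit$centroids), 2)
  expect_equal(unclass(fit$memberships), unclass(want), tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("repeat runs with identical seed and input are identical", {
  vol <- two_pop_volume(16, seed = 6)
  for (alg in c("fcm", "mskfcm")) {
    f1 <- fuzzy_cluster(vol, alg, clusters = 3,
                        init = init_spec("random", seed = 7))
    f2 <- fuzzy_cluster(vol, alg, clusters = 3,
                        init = init_spec("random", seed = 7))
    expect_identical(f1$centroids, f2$centroids)
    expect_identical(unclass(f1$memberships), unclass(f2$memberships))
  }
})

test_that("SFCM with p = 1, q = 0 reproduces the FCM trajectory", {
  vol <- two_pop_volume(12, seed = 9)
  init <- init_spec("random", seed = 4)
  f_s <- fuzzy_cluster(vol, "sfcm", clusters = 3, p = 1, q = 0, init = init)
  f_f <- fuzzy_cluster(vol, "fcm", clusters = 3, init = init)
  expect_equal(f_s$fits[[1]]$centroid_trace, f_f$fits[[1]]$centroid_trace,
               tolerance = 1e-9)
  expect_equal(f_s$iterations, f_f$iterations)
  expect_equal(unclass(f_s$memberships), unclass(f_f$memberships),
               tolerance = 1e-9, ignore_attr = TRUE)
})

test_that("MSKFCM with p = 1, q = 0 reproduces the KFCM trajectory", {
  vol <- two_pop_volume(12, seed = 10)
  init <- init_spec("random", seed = 4)
  k <- kernel_spec("gaussian", sigma = 300)
  f_m <- fuzzy_cluster(vol, "mskfcm", clusters = 3, p = 1, q = 0,
                       kernel = k, init = init)
  f_k <- fuzzy_cluster(vol, "kfcm", clusters = 3, kernel = k, init = init)
  expect_equal(f_m$fits[[1]]$centroid_trace, f_k$fits[[1]]$centroid_trace,
               tolerance = 1e-9)
  expect_equal(unclass(f_m$memberships), unclass(f_k$memberships),
               tolerance = 1e-9, ignore_attr = TRUE)
})

test_that("KFCM with a huge sigma tracks the FCM centroid trajectory", {
  vol <- two_pop_volume(32, seed = 3)
  init <- init_spec("samples", samples = list(-850, -50))
  f_k <- fuzzy_cluster(vol, "kfcm", clusters = 2, init = init,
                       kernel = kernel_spec("gaussian", sigma = 1e6))
  f_f <- fuzzy_cluster(vol, "fcm", clusters = 2, init = init)
  expect_lt(max(abs(f_k$centroids - f_f$centroids)), 1e-3)
})

test_that("SKFCM is continuous in alpha near the KFCM limit", {
  ph <- generate_phantom(phantom_spec(shape = c(16, 16, 1), noise_sd = 15,
                                      nodules = list(), vessels = list()))
  init <- init_spec("samples", samples = list(-850, -50))
  k <- kernel_spec("gaussian", sigma = 300, variance_scale = "sigma2")
  nb <- neighborhood_spec("2d", 3, include_center = FALSE)
  f_k <- fuzzy_cluster(ph$volume, "kfcm", clusters = 2, kernel = k,
                       init = init)
  dev <- vapply(c(1e-3, 1e-4), function(a) {
    f_a <- fuzzy_cluster(ph$volume, "skfcm", clusters = 2, alpha = a,
                         kernel = k, neighborhood = nb, init = init)
    n <- min(nrow(f_a$fits[[1]]$centroid_trace),
             nrow(f_k$fits[[1]]$centroid_trace))
    max(abs(f_a$fits[[1]]$centroid_trace[1:n, ] -
            f_k$fits[[1]]$centroid_trace[1:n, ]))
  }, numeric(1))
  # the penalty perturbs the trajectory at first order in alpha ...
  expect_equal(dev[1] / dev[2], 10, tolerance = 0.2)
  # ... and a small alpha stays within a small fraction of an HU
  expect_lt(dev[2], 1e-2)
})

test_that("SKFCM recovers both regions of a noisy two-region phantom", {
  ph <- generate_phantom(phantom_spec(shape = c(24, 24, 1), noise_sd = 20,
                                      nodules = list(list(center = c(9, 15,
                                                                     1),
                                                          radius = 3,
                                                          hu = -50)),
                                      vessels = list()))
  fit <- fuzzy_cluster(ph$volume, "skfcm", clusters = 2,
                       init = init_spec("samples",
                                        samples = list(-850, -50)))
  v <- sort(as.numeric(fit$centroids))
  expect_lt(abs(v[1] - -850), 15)
  expect_lt(abs(v[2] - -50), 15)
})

test_that("every solver keeps memberships valid and centroids in range", {
  vol <- two_pop_volume(12, seed = 13)
  rng <- range(vol$voxels)
  for (alg in c("fcm", "kfcm", "sfcm", "skfcm", "mskfcm")) {
    fit <- fuzzy_cluster(vol, alg, clusters = 3,
                         init = init_spec("random", seed = 1))
    expect_valid_memberships(fit$memberships)
    expect_true(all(fit$centroids >= rng[1] & fit$centroids <= rng[2]))
    expect_true(all(fit$iterations <= fit$params$max_iter))
  }
})

test_that("hitting max_iter reports non-convergence, not an error", {
  vol <- two_pop_volume(12, seed = 14)
  fit <- fuzzy_cluster(vol, "fcm", clusters = 3, max_iter = 1,
                       epsilon = 1e-12, init = init_spec("random", seed = 1))
  expect_false(fit$converged)
  expect_equal(fit$iterations, 1L)
})

test_that("3D MSKFCM on replicated slices labels like 2D on one slice", {
  ph <- generate_phantom(phantom_spec(shape = c(24, 24, 1), noise_sd = 20,
                                      nodules = list(list(center = c(9, 15,
                                                                     1),
                                                          radius = 3,
                                                          hu = -50)),
                                      vessels = list()))
  sl <- ph$volume$voxels[, , 1]
  vol3 <- ct_volume(array(rep(sl, 3), c(24, 24, 3)),
                    lung_mask = array(rep(ph$lung_mask[, , 1], 3),
                                      c(24, 24, 3)))
  init <- init_spec("samples", samples = phantom_samples)
  f2 <- fuzzy_cluster(ct_volume(sl, lung_mask = ph$lung_mask[, , 1]),
                      "mskfcm", clusters = 3,
                      neighborhood = neighborhood_spec("2d", 3),
                      init = init)
  f3 <- fuzzy_cluster(vol3, "mskfcm", clusters = 3,
                      neighborhood = neighborhood_spec("3d", 3),
                      init = init)
  lab2 <- defuzzify(f2)[, , 1]
  lab3 <- defuzzify(f3)[, , 2]
  expect_equal(lab2, lab3)
})

test_that("nodule-cluster selection follows the hint / midrange rules", {
  ph <- generate_phantom(phantom_spec())
  fit <- fuzzy_cluster(ph$volume, "mskfcm", clusters = 3,
                       init = init_spec("samples",
                                        samples = phantom_samples))
  # hint: nearest centroid
  expect_equal(select_nodule_cluster(fit, hint = -35),
               apply(fit$centroids, 2, function(v) which.min(abs(v + 35))))
  # no hint, c = 3: midrange centroid
  sel <- select_nodule_cluster(fit)
  for (j in seq_along(sel))
    expect_equal(fit$centroids[sel[j], j],
                 sort(fit$centroids[, j])[2])
  # the auto-selected cluster has the highest truth overlap of all clusters
  overlaps <- vapply(1:3, function(cl) {
    sum(roi_mask(fit, cluster = cl)$grid & ph$truth$grid)
  }, numeric(1))
  expect_equal(unique(sel), which.max(overlaps))
  # no hint, c != 3 is an explicit error
  fit2 <- fuzzy_cluster(ph$volume, "fcm", clusters = 2,
                        init = init_spec("samples",
                                         samples = list(-850, -50)))
  expect_error(select_nodule_cluster(fit2), "hint")
})

test_that("algorithm-irrelevant parameters and bad values are rejected", {
  vol <- two_pop_volume(8, seed = 1)
  expect_error(fuzzy_cluster(vol, "fcm", fuzzifier = 1), "m")
  expect_error(fuzzy_cluster(vol, "fcm", epsilon = 0), "epsilon")
  expect_error(fuzzy_cluster(vol, "skfcm", alpha = 1), "alpha")
  expect_error(fuzzy_cluster(vol, "skfcm",
                             neighborhood = neighborhood_spec("2d", 3)),
               "exclude")
})
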