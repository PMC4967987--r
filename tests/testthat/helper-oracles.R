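# Naive scalar-loop reference implementations of every membership, spatial,
# and centroid update, written independently of the package internals
# (explicit loops, inline kernel evaluation, explicit window enumeration).
# Used to check the vectorized implementations on tiny images.

o_gauss <- function(x, y, sigma, scale = "2sigma2") {
  den <- if (scale == "2sigma2") 2 * sigma^2 else sigma^2
  exp(-(x - y)^2 / den)
}

o_fcm_u <- function(x, v, m) {
  cc <- length(v); n <- length(x)
  u <- matrix(0, cc, n)
  for (k in seq_len(n)) {
    d <- abs(x[k] - v)
    if (any(d == 0)) {
      u[d == 0, k] <- 1 / sum(d == 0)
    } else {
      for (i in seq_len(cc))
        u[i, k] <- 1 / sum((d[i] / d)^(2 / (m - 1)))
    }
  }
  u
}

o_fcm_v <- function(x, u, m) {
  cc <- nrow(u)
  v <- numeric(cc)
  for (i in seq_len(cc))
    v[i] <- sum(u[i, ]^m * x) / sum(u[i, ]^m)
  v
}

o_kfcm_u <- function(x, v, m, sigma, scale = "2sigma2") {
  cc <- length(v); n <- length(x)
  u <- matrix(0, cc, n)
  for (k in seq_len(n)) {
    b <- 1 - o_gauss(x[k], v, sigma, scale)
    if (any(b == 0)) {
      u[b == 0, k] <- 1 / sum(b == 0)
    } else {
      w <- b^(-1 / (m - 1))
      u[, k] <- w / sum(w)
    }
  }
  u
}

o_kfcm_v <- function(x, v_prev, u, m, sigma, scale = "2sigma2") {
  cc <- nrow(u)
  v <- numeric(cc)
  for (i in seq_len(cc)) {
    kk <- o_gauss(x, v_prev[i], sigma, scale)
    v[i] <- sum(u[i, ]^m * kk * x) / sum(u[i, ]^m * kk)
  }
  v
}

# Explicit window enumeration on a rows x cols x slices grid; returns the
# linear indices of the in-bounds window voxels around (r, c, s).
o_window <- function(d, r, c, s, size, depth = 1L, include_center = TRUE) {
  h <- (size - 1) / 2; hd <- (depth - 1) / 2
  out <- integer(0)
  for (ds in -hd:hd) for (dc in -h:h) for (dr in -h:h) {
    rr <- r + dr; cc <- c + dc; ss <- s + ds
    if (rr < 1 || rr > d[1] || cc < 1 || cc > d[2] || ss < 1 || ss > d[3])
      next
    if (!include_center && dr == 0 && dc == 0 && ds == 0) next
    out <- c(out, rr + (cc - 1) * d[1] + (ss - 1) * d[1] * d[2])
  }
  out
}

# Spatial function over the eligible voxels `idx` (linear indices) of a grid.
o_spatial_h <- function(u, idx, d, size, depth = 1L, include_center = TRUE) {
  cc <- nrow(u); n <- length(idx)
  pos <- arrayInd(idx, d)
  col_of <- integer(prod(d)); col_of[idx] <- seq_len(n)
  h <- matrix(0, cc, n)
  for (j in seq_len(n)) {
    w <- o_window(d, pos[j, 1], pos[j, 2], pos[j, 3], size, depth,
                  include_center)
    w <- w[w %in% idx]
    for (i in seq_len(cc)) h[i, j] <- sum(u[i, col_of[w]])
  }
  h
}

o_spatial_u <- function(u, h, p, q) {
  cc <- nrow(u); n <- ncol(u)
  out <- matrix(0, cc, n)
  for (j in seq_len(n)) {
    w <- u[, j]^p * (if (q == 0) rep(1, cc) else h[, j]^q)
    out[, j] <- w / sum(w)
  }
  out
}

o_skfcm_u <- function(x, v, m, sigma, idx, d, size, depth, alpha,
                      scale = "sigma2") {
  cc <- length(v); n <- length(x)
  pos <- arrayInd(idx, d)
  col_of <- integer(prod(d)); col_of[idx] <- seq_len(n)
  u <- matrix(0, cc, n)
  for (k in seq_len(n)) {
    w <- o_window(d, pos[k, 1], pos[k, 2], pos[k, 3], size, depth, FALSE)
    w <- w[w %in% idx]
    nr <- max(length(w), 1)
    b <- numeric(cc)
    for (i in seq_len(cc)) {
      pen <- sum(1 - o_gauss(x[col_of[w]], v[i], sigma, scale))
      b[i] <- (1 - o_gauss(x[k], v[i], sigma, scale)) + alpha / nr * pen
    }
    if (any(b == 0)) {
      u[b == 0, k] <- 1 / sum(b == 0)
    } else {
      ww <- b^(-1 / (m - 1))
      u[, k] <- ww / sum(ww)
    }
  }
  u
}

o_skfcm_v <- function(x, v_prev, u, m, sigma, idx, d, size, depth, alpha,
                      scale = "sigma2") {
  cc <- length(v_prev); n <- length(x)
  pos <- arrayInd(idx, d)
  col_of <- integer(prod(d)); col_of[idx] <- seq_len(n)
  v <- numeric(cc)
  for (i in seq_len(cc)) {
    num <- 0; den <- 0
    for (k in seq_len(n)) {
      w <- o_window(d, pos[k, 1], pos[k, 2], pos[k, 3], size, depth, FALSE)
      w <- w[w %in% idx]
      nr <- max(length(w), 1)
      kk <- o_gauss(x[k], v_prev[i], sigma, scale)
      kn <- o_gauss(x[col_of[w]], v_prev[i], sigma, scale)
      num <- num + u[i, k]^m *
        (kk * x[k] + alpha / nr * sum(kn * x[col_of[w]]))
      den <- den + u[i, k]^m * (kk + alpha / nr * sum(kn))
    }
    v[i] <- num / den
  }
  v
}

as_mm <- function(u, idx = seq_len(ncol(u))) membership_matrix(u, idx)

# Random valid membership matrix (columns sum to 1).
random_memberships <- function(cc, n) {
  u <- matrix(stats::runif(cc * n), cc, n)
  sweep(u, 2, colSums(u), "/")
}

# Small random test volume with intensities on a CT-like scale.
random_volume <- function(d, seed, masked = FALSE) {
  set.seed(seed)
  vox <- array(stats::runif(prod(d), -1000, 100), d)
  mask <- if (masked) array(stats::runif(prod(d)) > 0.2, d) else NULL
  if (masked && !any(mask)) mask[1] <- TRUE
  ct_volume(vox, lung_mask = mask)
}

expect_valid_memberships <- function(u, tol = 1e-9) {
  expect_true(all(u >= -tol & u <= 1 + tol))
  expect_true(max(abs(colSums(unclass(u)) - 1)) <= tol)
}

# Operator sample sets matching the standard phantom's structures.
phantom_samples <- list(-850, -50, 40)
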