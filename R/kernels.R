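#' Kernel specification
#'
#' Describes the kernel function used by the kernelized algorithms (KFCM,
#' SKFCM, MSKFCM) to measure similarity between a voxel intensity and a
#' cluster centroid.  Two families are supported:
#'
#' * `gaussian`: `K(x, y) = exp(-(x - y)^2 / D)` with denominator
#'   `D = 2 * sigma^2` (`variance_scale = "2sigma2"`, the KFCM convention) or
#'   `D = sigma^2` (`variance_scale = "sigma2"`, the SKFCM convention).  The
#'   two conventions coincide under `sigma' = sigma * sqrt(2)`.
#' * `polynomial`: `K(x, y) = (x * y + b)^d` with integer degree `d >= 0`.
#'
#' `sigma` is on the intensity (HU) scale; values in the 150--750 range are
#' sensible for thoracic CT.
#'
#' @param family `"gaussian"` or `"polynomial"`.
#' @param sigma positive Gaussian width in HU.
#' @param variance_scale `"2sigma2"` or `"sigma2"`; Gaussian denominator
#'   convention.
#' @param b polynomial offset.
#' @param d non-negative integer polynomial degree.
#' @return An object of class `kernel_spec`.
#' @examples
#' k <- kernel_spec("gaussian", sigma = 300)
#' kernel_value(-600, -600, k)  # 1: self-similarity
#' @export
kernel_spec <- function(family = c("gaussian", "polynomial"), sigma = 300,
                        variance_scale = c("2sigma2", "sigma2"),
                        b = 1, d = 2L) {
  family <- match.arg(family)
  variance_scale <- match.arg(variance_scale)
  if (family == "gaussian") {
    if (!is_scalar_num(sigma) || sigma <= 0)
      stop_param("gaussian kernel requires sigma > 0 (got %s)",
                 format(sigma))
  } else {
    if (!is_count(d) || d < 0)
      stop_param("polynomial kernel requires a non-negative integer degree d")
    if (!is_scalar_num(b)) stop_param("polynomial offset b must be a number")
  }
  structure(list(family = family, sigma = as.numeric(sigma),
                 variance_scale = variance_scale,
                 b = as.numeric(b), d = as.integer(d)),
            class = "kernel_spec")
}

#' @export
print.kernel_spec <- function(x, ...) {
  if (x$family == "gaussian")
    cat(sprintf("gaussian kernel: sigma = %g HU, denominator %s\n", x$sigma,
                if (x$variance_scale == "2sigma2") "2*sigma^2" else "sigma^2"))
  else
    cat(sprintf("polynomial kernel: (x*y + %g)^%d\n", x$b, x$d))
  invisible(x)
}

#' Evaluate a kernel
#'
#' Vectorized over `x` and `y` (recycled).  The Gaussian kernel is symmetric,
#' equals 1 iff `x == y`, and decreases monotonically in `|x - y|`.
#'
#' @param x,y intensities (HU).
#' @param spec a [kernel_spec()].
#' @return numeric vector of kernel values.
#' @examples
#' s <- kernel_spec("gaussian", sigma = 100)
#' kernel_value(0, 100, s)  # exp(-0.5)
#' @export
kernel_value <- function(x, y, spec) {
  stopifnot(inherits(spec, "kernel_spec"))
  if (spec$family == "gaussian") {
    denom <- if (spec$variance_scale == "2sigma2") 2 * spec$sigma^2
             else spec$sigma^2
    exp(-(x - y)^2 / denom)
  } else {
    (x * y + spec$b)^spec$d
  }
}

# Gaussian denominator, used by the vectorized solver internals.
kernel_denominator <- function(spec) {
  if (spec$variance_scale == "2sigma2") 2 * spec$sigma^2 else spec$sigma^2
}

# c x n matrix of K(x_k, v_i) for scalar intensities x and centroids v.
kernel_matrix <- function(x, centroids, spec) {
  if (spec$family == "gaussian") {
    d2 <- outer(centroids, x, function(v, xx) (xx - v)^2)
    exp(-d2 / kernel_denominator(spec))
  } else {
    outer(centroids, x, function(v, xx) (xx * v + spec$b)^spec$d)
  }
}
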