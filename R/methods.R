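# S3 methods for fuzzy_fit objects.

#' @export
print.fuzzy_fit <- function(x, ...) {
  cat(sprintf("Fuzzy clustering fit (%s)\n", toupper(x$algorithm)))
  d <- dim(x$volume$voxels)
  cat(sprintf("  volume %d x %d x %d, %d eligible voxels, %d clusters\n",
              d[1], d[2], d[3], ncol(x$memberships), x$params$clusters))
  if (x$slice_wise) {
    cat(sprintf("  slice-wise fit over %d slices; iterations: %s\n",
                length(x$fits), paste(x$iterations, collapse = ", ")))
  } else {
    cat(sprintf("  %d iterations, %s\n", x$iterations,
                if (x$converged) "converged" else "NOT converged"))
  }
  cat("  centroids (HU):\n")
  print(round(x$centroids, 2))
  invisible(x)
}

#' @export
summary.fuzzy_fit <- function(object, ...) {
  lab <- defuzzify(object$memberships)
  sizes <- tabulate(lab, nbins = object$params$clusters)
  out <- list(algorithm = object$algorithm,
              centroids = object$centroids,
              cluster_sizes = sizes,
              iterations = object$iterations,
              converged = object$converged,
              final_objective = vapply(object$fits, function(f)
                if (length(f$objective_trace)) utils::tail(f$objective_trace,
                                                           1) else NA_real_,
                numeric(1)),
              mean_max_membership = mean(apply(unclass(object$memberships),
                                               2L, max)),
              params = object$params)
  class(out) <- "summary.fuzzy_fit"
  out
}

#' @export
print.summary.fuzzy_fit <- function(x, ...) {
  cat(sprintf("Fuzzy clustering fit (%s)\n", toupper(x$algorithm)))
  cat("  centroids (HU):\n")
  print(round(x$centroids, 2))
  cat("  crisp cluster sizes:", paste(x$cluster_sizes, collapse = ", "), "\n")
  cat(sprintf("  iterations: %s; converged: %s\n",
              paste(x$iterations, collapse = ", "), x$converged))
  cat(sprintf("  mean maximal membership: %.3f\n", x$mean_max_membership))
  invisible(x)
}

#' @export
coef.fuzzy_fit <- function(object, ...) {
  v <- object$centroids
  if (ncol(v) == 1L) drop(v) else v
}

#' @export
fitted.fuzzy_fit <- function(object, ...) object$memberships

#' Memberships of new intensities
#'
#' Evaluates the fitted model's (non-spatial) membership function at new
#' intensity values, against the fitted centroids.  For spatial algorithms
#' this is the intensity-driven part of the membership only: new isolated
#' intensities carry no neighborhood.
#'
#' @param object a [fuzzy_cluster()] fit.
#' @param newdata numeric vector of intensities (HU).
#' @param slice for slice-wise fits, which slice's centroids to use.
#' @param type `"memberships"` (matrix) or `"labels"` (argmax vector).
#' @param ... unused.
#' @export
predict.fuzzy_fit <- function(object, newdata, slice = 1L,
                              type = c("memberships", "labels"), ...) {
  type <- match.arg(type)
  v <- object$centroids[, slice]
  m <- object$params$fuzzifier
  u <- if (object$algorithm %in% c("fcm", "sfcm"))
    fcm_memberships(newdata, v, m)
  else
    kfcm_memberships(newdata, v, m, object$params$kernel)
  if (type == "labels") defuzzify(u) else u
}

#' @describeIn defuzzify label array for a fitted volume: integer cluster
#'   labels on the voxel grid, `NA` outside the lung mask.
#' @export
defuzzify.fuzzy_fit <- function(x, ...) {
  dims <- dim(x$volume$voxels)
  out <- array(NA_integer_, dims)
  out[attr(x$memberships, "voxel_index")] <- defuzzify(x$memberships)
  out
}

#' Plot a fitted segmentation
#'
#' Displays the crisp label map of one slice (base graphics).
#'
#' @param x a [fuzzy_cluster()] fit.
#' @param slice slice number to display.
#' @param ... passed to [graphics::image()].
#' @export
plot.fuzzy_fit <- function(x, slice = 1L, ...) {
  lab <- defuzzify(x)[, , slice]
  cc <- x$params$clusters
  lab[is.na(lab)] <- 0L
  graphics::image(t(lab[nrow(lab):1, , drop = FALSE]),
                  col = c("black", grDevices::hcl.colors(cc, "viridis")),
                  axes = FALSE, asp = 1,
                  main = sprintf("%s labels, slice %d", toupper(x$algorithm),
                                 slice), ...)
  invisible(x)
}
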