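#' Nodule mask
#'
#' A voxel mask aligned with a [ct_volume()].  Two semantics:
#' * `"binary"`: logical nodule / not-nodule.
#' * `"consensus"`: integer scores in `[0, 1000]` encoding the level of
#'   radiologist agreement that each voxel belongs to a nodule (1000 =
#'   unanimous yes, 0 = unanimous no).
#'
#' @param grid logical or numeric matrix/array (a matrix is treated as one
#'   slice).
#' @param semantics `"binary"` or `"consensus"`.
#' @return An object of class `nodule_mask` with elements `grid` (3D array)
#'   and `semantics`.
#' @export
nodule_mask <- function(grid, semantics = c("binary", "consensus")) {
  semantics <- match.arg(semantics)
  if (is.matrix(grid)) dim(grid) <- c(dim(grid), 1L)
  if (!is.array(grid) || length(dim(grid)) != 3L)
    stop_param("mask grid must be a matrix or 3D array")
  if (semantics == "binary") {
    grid <- array(as.logical(grid), dim(grid))
    if (anyNA(grid)) stop_param("binary mask must have no NA")
  } else {
    if (!is.numeric(grid) || anyNA(grid) || any(grid < 0 | grid > 1000))
      stop_param("consensus scores must lie in [0, 1000]")
    grid <- array(as.numeric(grid), dim(grid))
  }
  structure(list(grid = grid, semantics = semantics), class = "nodule_mask")
}

#' @export
print.nodule_mask <- function(x, ...) {
  d <- dim(x$grid)
  if (x$semantics == "binary")
    cat(sprintf("binary nodule_mask %dx%dx%d: %d positive voxels\n",
                d[1], d[2], d[3], sum(x$grid)))
  else
    cat(sprintf("consensus nodule_mask %dx%dx%d: scores in [%g, %g]\n",
                d[1], d[2], d[3], min(x$grid), max(x$grid)))
  invisible(x)
}

as_nodule_mask <- function(x, semantics = "binary") {
  if (inherits(x, "nodule_mask")) x else nodule_mask(x, semantics)
}

#' Threshold a consensus mask
#'
#' Converts a radiologist-consensus mask (scores 0--1000) to binary: a voxel
#' is positive iff its score is greater than or equal to `threshold`.  A
#' threshold of 800 keeps only voxels with strong agreement.
#'
#' @param mask a consensus-semantics [nodule_mask()].
#' @param threshold score cutoff in `[0, 1000]`.
#' @return a binary [nodule_mask()].
#' @export
consensus_filter <- function(mask, threshold = 800) {
  mask <- as_nodule_mask(mask, "consensus")
  if (mask$semantics != "consensus")
    stop_param(paste0("consensus_filter needs a consensus-semantics mask; ",
                      "a binary mask needs no filtering"))
  if (!is_scalar_num(threshold) || threshold < 0 || threshold > 1000)
    stop_param("threshold must lie in [0, 1000]")
  nodule_mask(mask$grid >= threshold, "binary")
}

#' Pixelwise TP/FP scoring of a predicted nodule mask
#'
#' True positives are nodule voxels labeled nodule; false positives are
#' voxels labeled nodule that belong to another structure.  Percentages:
#' `tp_pct = 100 * TP / |truth|` and, by default,
#' `fp_pct = 100 * FP / |predicted|` (the complement of precision).  The
#' alternative denominator `|domain \ truth|` is available via
#' `fp_denominator = "domain"`.  An empty truth yields `tp_pct = NA` (not
#' zero), so slices without a nodule stay visible in aggregations.
#'
#' @param predicted binary [nodule_mask()] (or logical array).
#' @param truth binary [nodule_mask()] (or logical array), same shape.
#' @param domain optional logical array restricting the evaluation (e.g. the
#'   lung mask); voxels outside it are ignored on both sides.
#' @param fp_denominator `"predicted"` or `"domain"`.
#' @param per_slice score each slice separately?
#' @return a data.frame of evaluation records with columns `slice`,
#'   `tp_count`, `fp_count`, `fn_count`, `tp_pct`, `fp_pct`,
#'   `fp_denominator`, `domain` (one row, or one per slice).
#' @examples
#' truth <- matrix(FALSE, 4, 4); truth[2:3, 2:3] <- TRUE
#' tp_fp_rates(truth, truth)  # tp_pct 100, fp_pct 0
#' @export
tp_fp_rates <- function(predicted, truth, domain = NULL,
                        fp_denominator = c("predicted", "domain"),
                        per_slice = FALSE) {
  fp_denominator <- match.arg(fp_denominator)
  predicted <- as_nodule_mask(predicted)$grid
  truth <- as_nodule_mask(truth)$grid
  if (!identical(dim(predicted), dim(truth)))
    stop_param("predicted (%s) and truth (%s) shapes differ",
               paste(dim(predicted), collapse = "x"),
               paste(dim(truth), collapse = "x"))
  if (!is.null(domain)) {
    if (is.matrix(domain)) dim(domain) <- c(dim(domain), 1L)
    if (!identical(dim(domain), dim(truth)))
      stop_param("domain shape does not match the masks")
    domain <- array(as.logical(domain), dim(truth))
  }
  slices <- if (per_slice) seq_len(dim(truth)[3L]) else NA_integer_
  rows <- lapply(slices, function(s) {
    if (is.na(s)) {
      p <- predicted; tr <- truth
      dm <- if (is.null(domain)) array(TRUE, dim(truth)) else domain
    } else {
      p <- predicted[, , s]; tr <- truth[, , s]
      dm <- if (is.null(domain)) matrix(TRUE, dim(truth)[1L], dim(truth)[2L])
            else domain[, , s]
    }
    p <- p & dm; tr <- tr & dm
    tp <- sum(p & tr)
    fp <- sum(p & !tr)
    fn <- sum(!p & tr)
    npos <- tp + fn
    npred <- tp + fp
    tp_pct <- if (npos == 0L) NA_real_ else 100 * tp / npos
    fp_den <- if (fp_denominator == "predicted") npred else sum(dm & !tr)
    fp_pct <- if (fp_den == 0L) if (fp == 0L) 0 else NA_real_
              else 100 * fp / fp_den
    data.frame(slice = s, tp_count = tp, fp_count = fp, fn_count = fn,
               tp_pct = tp_pct, fp_pct = fp_pct,
               fp_denominator = fp_denominator,
               domain = if (is.null(domain)) "full" else "domain")
  })
  do.call(rbind, rows)
}

#' Bowyer-style parameter sweep
#'
#' Runs one clustering algorithm over a grid of parameter combinations,
#' selects the nodule cluster of each fit, and scores the resulting ROI mask
#' per slice against the ground truth.  Sampling the parameter space broadly
#' enough traces out the algorithm's attainable TP-vs-FP tradeoffs, the way
#' an ROC curve would for a thresholded detector.  A solver failure on one
#' combination yields a record with `NA` scores and the error message, never
#' a sweep abort.  Output ordering is deterministic: grid order, then slice
#' order.
#'
#' @param volume a [ct_volume()].
#' @param truth binary [nodule_mask()].
#' @param algorithm algorithm id (see [fuzzy_cluster()]).
#' @param grid list of named lists of [fuzzy_cluster()] arguments to
#'   override per combination (e.g. `list(list(kernel = kernel_spec(sigma =
#'   150)), ...)`).
#' @param init an [init_spec()], shared by all combinations.
#' @param hint optional nodule-intensity hint for cluster selection.
#' @param fp_denominator passed to [tp_fp_rates()].
#' @param ... further fixed arguments to [fuzzy_cluster()].
#' @return a data.frame: one row per (combination, slice), with a `combo`
#'   index, a human-readable `params` string, the algorithm id, the TP/FP
#'   fields of [tp_fp_rates()], and an `error` column (`NA` on success).
#' @export
parameter_sweep <- function(volume, truth, algorithm, grid,
                            init = init_spec(), hint = NULL,
                            fp_denominator = "predicted", ...) {
  volume <- as_ct_volume(volume)
  truth <- as_nodule_mask(truth)
  if (!is.list(grid) || length(grid) < 1L)
    stop_param("grid must be a nonempty list of parameter combinations")
  fixed <- list(...)
  out <- lapply(seq_along(grid), function(g) {
    combo <- grid[[g]]
    label <- describe_params(combo)
    rec <- tryCatch({
      args <- c(list(volume = volume, algorithm = algorithm, init = init),
                combo, fixed[setdiff(names(fixed), names(combo))])
      fit <- do.call(fuzzy_cluster, args)
      pred <- roi_mask(fit, hint = hint)
      r <- tp_fp_rates(pred, truth, domain = volume$lung_mask,
                       fp_denominator = fp_denominator, per_slice = TRUE)
      r$error <- NA_character_
      r
    }, error = function(e) {
      data.frame(slice = NA_integer_, tp_count = NA_integer_,
                 fp_count = NA_integer_, fn_count = NA_integer_,
                 tp_pct = NA_real_, fp_pct = NA_real_,
                 fp_denominator = fp_denominator, domain = NA_character_,
                 error = conditionMessage(e))
    })
    rec$combo <- g
    rec$params <- label
    rec$algorithm <- algorithm
    rec
  })
  res <- do.call(rbind, out)
  res[, c("algorithm", "combo", "params", "slice", "tp_count", "fp_count",
          "fn_count", "tp_pct", "fp_pct", "fp_denominator", "domain",
          "error")]
}

describe_params <- function(combo) {
  if (length(combo) == 0L) return("(defaults)")
  paste(vapply(names(combo), function(nm) {
    val <- combo[[nm]]
    if (inherits(val, "kernel_spec"))
      sprintf("sigma=%g", val$sigma)
    else if (inherits(val, "neighborhood_spec"))
      sprintf("window=%s%dx%d", val$mode, val$size, val$size)
    else sprintf("%s=%s", nm, paste(format(val), collapse = ","))
  }, character(1)), collapse = " ")
}

#' TP-vs-FP tradeoff table
#'
#' Orders sweep records for reading off operating points: within each
#' algorithm, ascending false-positive percentage and, at equal FP,
#' descending true-positive percentage.  The result is order-invariant in
#' the input records.
#'
#' @param records a data.frame from [parameter_sweep()] or [tp_fp_rates()].
#' @return the reordered data.frame.
#' @export
tradeoff_table <- function(records) {
  if (!is.data.frame(records) || nrow(records) < 1L)
    stop_param("records must be a nonempty data.frame")
  if (is.null(records$algorithm)) records$algorithm <- ""
  key <- order(records$algorithm, records$fp_pct, -records$tp_pct,
               records$combo %||% seq_len(nrow(records)),
               records$slice %||% seq_len(nrow(records)),
               na.last = TRUE)
  out <- records[key, , drop = FALSE]
  rownames(out) <- NULL
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Scatter plot of TP-vs-FP tradeoffs
#'
#' @param records sweep records.
#' @param ... passed to [graphics::plot()].
#' @export
plot_tradeoff <- function(records, ...) {
  ok <- is.finite(records$tp_pct) & is.finite(records$fp_pct)
  graphics::plot(records$fp_pct[ok], records$tp_pct[ok],
                 xlab = "FP (%)", ylab = "TP (%)",
                 xlim = c(0, max(5, records$fp_pct[ok])), ylim = c(0, 100),
                 pch = 19, ...)
  invisible(records)
}
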