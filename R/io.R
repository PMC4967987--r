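# Volume and annotation I/O.
#
# Supported volume formats:
#   - NIfTI (.nii / .nii.gz) via RNifti: lossless for HU data, the
#     preferred interchange format.
#   - TIFF stacks (multi-page .tif/.tiff, or one file per slice) via the
#     tiff package, 16-bit: HU values are stored as (hu + 1024) / 65535
#     and recovered exactly for integer HU in [-1024, 3071].
#   - PNG stacks via the png package: 8-bit only on write, so PNG output is
#     a lossy visualization format; reads map gray levels back to the
#     12-bit HU range.

HU_MIN <- -1024
HU_MAX <- 3071

#' Read a CT volume
#'
#' @param path a NIfTI file, a (multi-page) TIFF file, or a character vector
#'   of per-slice PNG/TIFF files ordered by slice; a directory is read as an
#'   alphabetically ordered slice stack.
#' @param format `"nifti"`, `"tiff"`, `"png"`, or `NULL` to infer from the
#'   file extension.
#' @param lung_mask optional path of a volume of the same shape read as a
#'   nonzero-is-eligible mask.
#' @return a [ct_volume()].
#' @export
read_volume <- function(path, format = NULL, lung_mask = NULL) {
  if (length(path) == 1L && dir.exists(path)) {
    path <- list.files(path, pattern = "\\.(png|tif|tiff)$",
                       full.names = TRUE, ignore.case = TRUE)
    if (length(path) == 0L) stop_param("no image slices found in directory")
    path <- sort(path)
  }
  if (is.null(format)) format <- infer_format(path[1L])
  vol <- switch(format,
    nifti = read_nifti_volume(path),
    tiff = if (length(path) == 1L) read_tiff_volume(path)
           else read_stack(path, function(p) read_tiff_pages(p)[[1L]]),
    png = read_stack(path, read_png_slice),
    stop_param("unsupported format '%s' for %s", format, path[1L])
  )
  if (!is.null(lung_mask)) {
    m <- read_volume(lung_mask)
    vol <- ct_volume(vol$voxels, vol$spacing, m$voxels != 0)
  }
  vol
}

infer_format <- function(path) {
  ext <- tolower(tools::file_ext(sub("\\.gz$", "", path)))
  switch(ext,
         nii = "nifti",
         tif = , tiff = "tiff",
         png = "png",
         stop_param("cannot infer volume format of '%s'", path))
}

read_nifti_volume <- function(path) {
  if (!file.exists(path)) stop_param("no such file: %s", path)
  img <- RNifti::readNifti(path)
  a <- as.array(img)
  if (length(dim(a)) == 2L) dim(a) <- c(dim(a), 1L)
  sp <- RNifti::pixdim(img)
  if (length(sp) < 3L) sp <- c(sp, rep(1, 3L - length(sp)))
  ct_volume(a, spacing = sp[1:3])
}

read_stack <- function(paths, reader) {
  slices <- lapply(paths, reader)
  d <- dim(slices[[1L]])
  for (s in slices)
    if (!identical(dim(s), d))
      stop_param("slice dimensions differ within the stack")
  vox <- array(0, c(d, length(slices)))
  for (i in seq_along(slices)) vox[, , i] <- slices[[i]]
  ct_volume(vox)
}

read_tiff_pages <- function(path) {
  if (!file.exists(path)) stop_param("no such file: %s", path)
  pages <- tiff::readTIFF(path, all = TRUE)
  lapply(pages, function(p) {
    if (length(dim(p)) == 3L) p <- p[, , 1L]
    p * 65535 + HU_MIN
  })
}

read_tiff_volume <- function(path) {
  mats <- read_tiff_pages(path)
  vox <- array(0, c(dim(mats[[1L]]), length(mats)))
  for (i in seq_along(mats)) vox[, , i] <- mats[[i]]
  ct_volume(vox)
}

read_png_slice <- function(path) {
  if (!file.exists(path)) stop_param("no such file: %s", path)
  p <- png::readPNG(path)
  if (length(dim(p)) == 3L) p <- p[, , 1L]
  p * (HU_MAX - HU_MIN) + HU_MIN
}

#' Write a CT volume
#'
#' NIfTI keeps HU values exactly; TIFF stores `(hu + 1024) / 65535` at
#' 16 bits (exact for integer HU); PNG is 8-bit grayscale, for display only.
#'
#' @param volume a [ct_volume()] or array.
#' @param path output file; format inferred from the extension unless given.
#'   For PNG/TIFF with multiple slices, `%d`-style paths (e.g.
#'   `slice_%02d.png`) write one file per slice (TIFF without a pattern
#'   writes a multi-page file).
#' @param format `"nifti"`, `"tiff"`, or `"png"`.
#' @return `path`, invisibly.
#' @export
write_volume <- function(volume, path, format = NULL) {
  volume <- as_ct_volume(volume)
  if (is.null(format)) format <- infer_format(path)
  vox <- volume$voxels
  switch(format,
    nifti = {
      img <- RNifti::asNifti(vox, pixdim = volume$spacing)
      RNifti::writeNifti(img, path)
    },
    tiff = {
      scaled <- (pmin(pmax(vox, HU_MIN), HU_MIN + 65535) - HU_MIN) / 65535
      if (grepl("%", path)) {
        for (s in seq_len(dim(vox)[3L]))
          tiff::writeTIFF(scaled[, , s], sprintf(path, s),
                          bits.per.sample = 16L)
      } else {
        pages <- lapply(seq_len(dim(vox)[3L]), function(s) scaled[, , s])
        tiff::writeTIFF(pages, path, bits.per.sample = 16L)
      }
    },
    png = {
      scaled <- (pmin(pmax(vox, HU_MIN), HU_MAX) - HU_MIN) / (HU_MAX - HU_MIN)
      if (dim(vox)[3L] > 1L && !grepl("%", path))
        stop_param("PNG needs a %%d-style path for multi-slice volumes")
      for (s in seq_len(dim(vox)[3L])) {
        target <- if (grepl("%", path)) sprintf(path, s) else path
        png::writePNG(scaled[, , s], target)
      }
    },
    stop_param("unsupported output format '%s'", format)
  )
  invisible(path)
}

#' Parse an LIDC-dialect XML nodule annotation
#'
#' Reads the reading sessions of an LIDC-style annotation file and rasterizes
#' each nodule's per-slice contour (`edgeMap` x/y coordinates, 0-based) into
#' the volume grid.  Contour pixels themselves count as nodule, and the
#' enclosed interior is filled.  With several reading sessions, each voxel's
#' vote count is scaled to the 0--1000 consensus range
#' (`round(1000 * votes / sessions)`; with 4 readers: 0/250/500/750/1000).
#' A file declaring the absence of nodules yields an empty mask.
#'
#' @param path XML file.
#' @param dim volume dimensions `(rows, cols, slices)`.
#' @param slice_z optional numeric z-position per slice, matched against each
#'   contour's `imageZposition`; by default contours carry 1-based
#'   `sliceIndex` elements instead.
#' @return a consensus-semantics [nodule_mask()] (binary thresholding is the
#'   caller's choice via [consensus_filter()]).
#' @export
parse_lidc_xml <- function(path, dim, slice_z = NULL) {
  if (!file.exists(path)) stop_param("no such file: %s", path)
  doc <- xml2::read_xml(path)
  ns_free <- xml2::xml_ns_strip(doc)
  sessions <- xml2::xml_find_all(doc, ".//readingSession")
  if (length(sessions) == 0L)
    stop_param("no readingSession elements in %s", path)
  votes <- array(0L, dim)
  for (ses in sessions) {
    hit <- array(FALSE, dim)
    nods <- xml2::xml_find_all(ses, ".//unblindedReadNodule")
    for (nod in nods) {
      for (roi in xml2::xml_find_all(nod, ".//roi")) {
        s <- roi_slice_index(roi, slice_z)
        if (is.na(s) || s < 1L || s > dim[3L])
          stop_param("contour references slice outside the volume (%s)",
                     format(s))
        em <- xml2::xml_find_all(roi, ".//edgeMap")
        xs <- as.numeric(xml2::xml_text(
          xml2::xml_find_first(em, "./xCoord")))
        ys <- as.numeric(xml2::xml_text(
          xml2::xml_find_first(em, "./yCoord")))
        if (anyNA(xs) || anyNA(ys))
          stop_param("malformed edgeMap in %s", path)
        # LIDC: x = column, y = row, both 0-based
        cols <- xs + 1L; rows <- ys + 1L
        if (any(rows < 1 | rows > dim[1L] | cols < 1 | cols > dim[2L]))
          stop_param("contour pixel outside the volume in %s", path)
        filled <- fill_contour(rows, cols, dim[1:2])
        hit[, , s] <- hit[, , s] | filled
      }
    }
    votes <- votes + hit
  }
  score <- round(1000 * votes / length(sessions))
  nodule_mask(score, "consensus")
}

roi_slice_index <- function(roi, slice_z) {
  si <- xml2::xml_find_first(roi, "./sliceIndex")
  if (!inherits(si, "xml_missing"))
    return(as.integer(xml2::xml_text(si)))
  zp <- xml2::xml_find_first(roi, "./imageZposition")
  if (inherits(zp, "xml_missing") || is.null(slice_z)) return(NA_integer_)
  z <- as.numeric(xml2::xml_text(zp))
  which.min(abs(slice_z - z))
}

# Rasterize a pixel-chain contour: the listed boundary pixels plus the
# even-odd interior of the polygon through the pixel centres.
fill_contour <- function(rows, cols, d) {
  out <- matrix(FALSE, d[1L], d[2L])
  out[cbind(rows, cols)] <- TRUE
  n <- length(rows)
  if (n >= 3L) {
    rmin <- max(1L, floor(min(rows))); rmax <- min(d[1L], ceiling(max(rows)))
    cmin <- max(1L, floor(min(cols))); cmax <- min(d[2L], ceiling(max(cols)))
    nxt <- c(seq_len(n)[-1L], 1L)
    for (r in rmin:rmax) {
      for (cc in cmin:cmax) {
        if (out[r, cc]) next
        # pixels lying on a polygon edge count as nodule (contour pixels
        # are constituent pixels), then even-odd ray cast along +col
        on_edge <- FALSE
        cross <- 0L
        for (e in seq_len(n)) {
          r1 <- rows[e]; c1 <- cols[e]
          r2 <- rows[nxt[e]]; c2 <- cols[nxt[e]]
          len2 <- (r2 - r1)^2 + (c2 - c1)^2
          if (len2 > 0) {
            tt <- ((r - r1) * (r2 - r1) + (cc - c1) * (c2 - c1)) / len2
            if (tt >= 0 && tt <= 1) {
              perp <- abs((r - r1) * (c2 - c1) - (cc - c1) * (r2 - r1)) /
                sqrt(len2)
              if (perp < 1e-9) { on_edge <- TRUE; break }
            }
          }
          if ((r1 > r) != (r2 > r)) {
            cint <- c1 + (r - r1) / (r2 - r1) * (c2 - c1)
            if (cint > cc) cross <- cross + 1L
          }
        }
        if (on_edge || cross %% 2L == 1L) out[r, cc] <- TRUE
      }
    }
  }
  out
}

#' Write segmentation outputs
#'
#' Writes, under `dir`: the crisp label map (`labels.nii`, 0 = outside the
#' lung mask), the selected-cluster ROI mask (`roi_mask.nii`), a
#' per-iteration trace (`trace.csv`: fit, iteration, centroids, objective,
#' max centroid change), and a plain-text `run_metadata.txt` sidecar listing
#' every parameter so the run can be reproduced.  All outputs are
#' deterministic functions of the fit (no timestamps).
#'
#' @param fit a [fuzzy_cluster()] fit.
#' @param dir output directory (created if needed).
#' @param cluster,hint forwarded to [roi_mask()].
#' @return invisibly, the named character vector of files written.
#' @export
write_outputs <- function(fit, dir, cluster = NULL, hint = NULL) {
  stopifnot(inherits(fit, "fuzzy_fit"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  labels <- defuzzify(fit)
  labels[is.na(labels)] <- 0L
  f_lab <- file.path(dir, "labels.nii")
  write_volume(ct_volume(labels, fit$volume$spacing), f_lab)
  roi <- roi_mask(fit, cluster = cluster, hint = hint)
  f_roi <- file.path(dir, "roi_mask.nii")
  write_volume(ct_volume(roi$grid + 0, fit$volume$spacing), f_roi)

  tr <- do.call(rbind, lapply(seq_along(fit$fits), function(j) {
    f <- fit$fits[[j]]
    it <- seq_len(f$iterations)
    data.frame(fit = j, iteration = it,
               objective = f$objective_trace,
               max_delta_v = f$delta_trace,
               matrix(t(f$centroid_trace[it + 1L, , drop = FALSE]),
                      ncol = nrow(fit$centroids), byrow = TRUE,
                      dimnames = list(NULL,
                        paste0("v", seq_len(nrow(fit$centroids))))))
  }))
  f_tr <- file.path(dir, "trace.csv")
  utils::write.csv(tr, f_tr, row.names = FALSE)

  f_meta <- file.path(dir, "run_metadata.txt")
  writeLines(run_metadata_lines(fit), f_meta)
  invisible(c(labels = f_lab, roi = f_roi, trace = f_tr,
              metadata = f_meta))
}

run_metadata_lines <- function(fit) {
  p <- fit$params
  k <- p$kernel; nb <- p$neighborhood; ini <- p$init
  c(sprintf("package_version=%s",
            as.character(utils::packageVersion("fuzzyCT"))),
    sprintf("algorithm=%s", fit$algorithm),
    sprintf("clusters=%d", p$clusters),
    sprintf("fuzzifier=%g", p$fuzzifier),
    sprintf("epsilon=%g", p$epsilon),
    sprintf("max_iter=%d", p$max_iter),
    sprintf("kernel_family=%s", k$family),
    sprintf("sigma=%g", k$sigma),
    sprintf("variance_scale=%s", k$variance_scale),
    sprintf("kernel_b=%g", k$b),
    sprintf("kernel_d=%d", k$d),
    sprintf("window_mode=%s", nb$mode),
    sprintf("window_size=%d", nb$size),
    sprintf("window_depth=%d", nb$depth),
    sprintf("include_center=%s", tolower(nb$include_center)),
    sprintf("p=%g", p$p),
    sprintf("q=%g", p$q),
    sprintf("alpha=%g", p$alpha),
    sprintf("init_mode=%s", ini$mode),
    sprintf("seed=%d", ini$seed),
    sprintf("slice_wise=%s", tolower(fit$slice_wise)),
    sprintf("iterations=%s", paste(fit$iterations, collapse = ",")),
    sprintf("converged=%s", tolower(fit$converged)))
}

#' Read a key=value configuration file
#'
#' One `key=value` pair per line; blank lines and `#` comments ignored.
#' Used for CLI run configuration and sweep grids.
#'
#' @param path file path.
#' @return named character vector.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop_param("no such file: %s", path)
  lines <- trimws(readLines(path, warn = FALSE))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  kv <- regmatches(lines, regexec("^([^=]+)=(.*)$", lines))
  bad <- vapply(kv, length, integer(1)) != 3L
  if (any(bad)) stop_param("malformed config line: %s", lines[bad][1L])
  stats::setNames(vapply(kv, `[`, character(1), 3L),
                  trimws(vapply(kv, `[`, character(1), 2L)))
}
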