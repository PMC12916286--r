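#' Calibrated image channel
#'
#' The substrate of every quantification recipe: a non-negative intensity
#' raster (2D `rows x cols` or 3D `rows x cols x planes`) with its physical
#' pixel calibration and a channel-role tag.  All physical thresholds in the
#' package are specified in micrometres and converted through the
#' calibration, so `calib_xy` is mandatory.
#'
#' @param pixels numeric matrix (2D) or 3D array of finite, non-negative
#'   intensities (arbitrary fluorescence units).
#' @param calib_xy pixel size in um per pixel (> 0).
#' @param calib_z plane spacing in um per plane (> 0); required for 3D data.
#' @param role channel role, one of `"dapi"`, `"map2"`, `"tdp43"`,
#'   `"c9orf72"`, `"p62"`, `"gh2ax"`, `"fish"`, `"gfp"`, `"unknown"`.
#' @return an object of class `image_channel`.
#' @examples
#' img <- image_channel(matrix(runif(100), 10), calib_xy = 0.1, role = "dapi")
#' img
#' @export
image_channel <- function(pixels, calib_xy, calib_z = NULL, role = "unknown") {
  roles <- c("dapi", "map2", "tdp43", "c9orf72", "p62", "gh2ax", "fish",
             "gfp", "unknown")
  role <- match.arg(role, roles)
  if (!is.numeric(pixels)) stop("pixels must be numeric")
  nd <- length(dim(pixels))
  if (is.null(dim(pixels)) || !(nd %in% 2:3))
    stop("pixels must be a 2D matrix or 3D array")
  if (any(!is.finite(pixels))) stop("intensities must be finite")
  if (any(pixels < 0)) stop("intensities must be >= 0")
  if (!is.numeric(calib_xy) || length(calib_xy) != 1L || calib_xy <= 0)
    stop("calib_xy must be a single positive number (um per pixel)")
  if (nd == 3L) {
    if (is.null(calib_z)) stop("calib_z is required for 3D data")
    if (!is.numeric(calib_z) || length(calib_z) != 1L || calib_z <= 0)
      stop("calib_z must be a single positive number (um per plane)")
  }
  structure(
    list(pixels = pixels, calib_xy = as.numeric(calib_xy),
         calib_z = if (is.null(calib_z)) NULL else as.numeric(calib_z),
         role = role),
    class = "image_channel")
}

#' @export
print.image_channel <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf("<image_channel> role=%s  %s px  calib_xy=%g um/px%s\n",
              x$role, paste(d, collapse = "x"), x$calib_xy,
              if (!is.null(x$calib_z)) sprintf("  calib_z=%g um", x$calib_z)
              else ""))
  cat(sprintf("  intensity range [%g, %g]\n", min(x$pixels), max(x$pixels)))
  invisible(x)
}

#' Binary mask
#'
#' A boolean raster sharing the shape and calibration of its source
#' [image_channel()].  Masks carry a provenance list recording the operations
#' (and threshold values) that produced them.
#'
#' @param pixels logical matrix/array (or numeric, coerced via `> 0`).
#' @param calib_xy um per pixel.
#' @param calib_z um per plane for 3D masks.
#' @param provenance named list of processing records.
#' @return object of class `binary_mask`.
#' @export
binary_mask <- function(pixels, calib_xy, calib_z = NULL,
                        provenance = list()) {
  if (is.numeric(pixels)) {
    d <- dim(pixels); pixels <- pixels > 0; dim(pixels) <- d
  }
  if (!is.logical(pixels) || is.null(dim(pixels)))
    stop("pixels must be a logical matrix or array")
  if (calib_xy <= 0) stop("calib_xy must be positive")
  structure(list(pixels = pixels, calib_xy = as.numeric(calib_xy),
                 calib_z = if (is.null(calib_z)) NULL else as.numeric(calib_z),
                 provenance = provenance),
            class = "binary_mask")
}

#' @export
print.binary_mask <- function(x, ...) {
  cat(sprintf("<binary_mask> %s px  calib_xy=%g um/px  foreground=%d px (%.3g um^2)\n",
              paste(dim(x$pixels), collapse = "x"), x$calib_xy,
              sum(x$pixels), sum(x$pixels) * x$calib_xy^2))
  if (length(x$provenance))
    cat("  provenance:", paste(names(x$provenance), collapse = " -> "), "\n")
  invisible(x)
}

#' Labeled regions
#'
#' Integer raster with 0 = background and 1..K = objects.  Labels form a
#' contiguous set; each positive label is one connected component unless
#' produced by watershed splitting.
#'
#' @param labels integer matrix/array of labels.
#' @param calib_xy um per pixel.
#' @param calib_z um per plane for 3D data.
#' @param provenance named list of processing records.
#' @return object of class `labeled_regions`.
#' @export
labeled_regions <- function(labels, calib_xy, calib_z = NULL,
                            provenance = list()) {
  if (!is.numeric(labels) || is.null(dim(labels)))
    stop("labels must be an integer matrix or array")
  d <- dim(labels)
  labels <- as.integer(round(labels)); dim(labels) <- d
  if (any(labels < 0)) stop("labels must be >= 0")
  u <- sort(unique(labels[labels > 0L]))
  if (length(u) && !identical(u, seq_len(max(labels))))
    stop("labels must form a contiguous set 1..K")
  structure(list(labels = labels, calib_xy = as.numeric(calib_xy),
                 calib_z = if (is.null(calib_z)) NULL else as.numeric(calib_z),
                 provenance = provenance),
            class = "labeled_regions")
}

#' @export
print.labeled_regions <- function(x, ...) {
  cat(sprintf("<labeled_regions> %s px  calib_xy=%g um/px  %d object(s)\n",
              paste(dim(x$labels), collapse = "x"), x$calib_xy,
              n_labels(x)))
  invisible(x)
}

#' Number of labeled objects
#' @param x a `labeled_regions` object.
#' @return integer count of positive labels.
#' @export
n_labels <- function(x) {
  stopifnot(inherits(x, "labeled_regions"))
  as.integer(max(x$labels, 0L))
}

## internal: connected components of a logical raster, physical-units aware
label_components <- function(px, connectivity = 8L) {
  d <- dim(px)
  if (length(d) == 2L) {
    storage.mode(px) <- "logical"
    .cc_label2d(px, as.integer(connectivity))
  } else {
    .cc_label3d(as.logical(px), as.integer(d), as.integer(connectivity))
  }
}

## internal: drop labels, keep selected ones, relabel contiguously
relabel_keep <- function(lab, keep) {
  d <- dim(lab)
  map <- integer(max(lab, 0L) + 1L)      # map[old+1] -> new
  map[keep + 1L] <- seq_along(keep)
  out <- map[lab + 1L]
  dim(out) <- d
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
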