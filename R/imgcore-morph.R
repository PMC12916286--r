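#' Remove small particles by equivalent-circle radius
#'
#' Deletes connected components (8-connectivity) whose equivalent-circle
#' radius `sqrt(area / pi)` falls below `min_radius_um`.  The comparison is
#' strict by default (a particle exactly at the radius is retained), matching
#' the "radius smaller than" phrasing of the recipes; set `inclusive = TRUE`
#' for the one recipe that removes particles "<= 5 um radius".
#'
#' @param mask a calibrated [binary_mask()].
#' @param min_radius_um minimum retained equivalent radius in um (> 0).
#' @param inclusive if `TRUE`, particles exactly at the radius are removed too.
#' @return a [binary_mask()] with small components removed.
#' @export
remove_small_by_radius <- function(mask, min_radius_um, inclusive = FALSE) {
  stopifnot(inherits(mask, "binary_mask"))
  if (min_radius_um <= 0) stop("min_radius_um must be positive")
  min_area <- pi * min_radius_um^2
  nq_remove_small(mask, min_area, inclusive,
                  record = list(op = "remove_small_by_radius",
                                min_radius_um = min_radius_um,
                                inclusive = inclusive))
}

#' Remove small particles by area
#'
#' Deletes connected components (8-connectivity) with area strictly below
#' `min_area_um2`.
#'
#' @param mask a calibrated [binary_mask()].
#' @param min_area_um2 minimum retained area in um^2 (> 0).
#' @return a [binary_mask()].
#' @export
remove_small_by_area <- function(mask, min_area_um2) {
  stopifnot(inherits(mask, "binary_mask"))
  if (min_area_um2 <= 0) stop("min_area_um2 must be positive")
  nq_remove_small(mask, min_area_um2, FALSE,
                  record = list(op = "remove_small_by_area",
                                min_area_um2 = min_area_um2))
}

nq_remove_small <- function(mask, min_area_um2, inclusive, record) {
  lab <- label_components(mask$pixels, 8L)
  k <- max(lab, 0L)
  px <- mask$pixels
  if (k > 0L) {
    areas <- tabulate(lab[lab > 0L], k) * mask$calib_xy^2
    drop <- if (inclusive) areas <= min_area_um2 else areas < min_area_um2
    if (any(drop)) px[lab %in% which(drop)] <- FALSE
  }
  binary_mask(px, mask$calib_xy, mask$calib_z,
              provenance = c(mask$provenance, list(remove_small = record)))
}

#' Fill enclosed holes up to a maximum area
#'
#' Background components (4-connectivity) fully enclosed by foreground and
#' with area at most `max_area_um2` become foreground; larger holes and
#' background touching the image border are never filled.
#'
#' @param mask a calibrated [binary_mask()].
#' @param max_area_um2 largest hole area filled, in um^2; `Inf` fills all
#'   enclosed holes (the plain "fill holes" command).
#' @return a [binary_mask()].
#' @export
fill_holes_max_area <- function(mask, max_area_um2) {
  stopifnot(inherits(mask, "binary_mask"))
  px <- mask$pixels
  bg <- label_components(!px, 4L)
  k <- max(bg, 0L)
  if (k > 0L) {
    nr <- nrow(bg); nc <- ncol(bg)
    border <- unique(c(bg[1, ], bg[nr, ], bg[, 1], bg[, nc]))
    areas <- tabulate(bg[bg > 0L], k) * mask$calib_xy^2
    fill <- setdiff(which(areas <= max_area_um2), border)
    if (length(fill)) px[bg %in% fill] <- TRUE
  }
  binary_mask(px, mask$calib_xy, mask$calib_z,
              provenance = c(mask$provenance,
                             list(fill_holes = list(max_area_um2 = max_area_um2))))
}

#' Split touching objects by watershed
#'
#' Labels the mask's foreground and splits touching convex blobs at the
#' ridge lines of the Euclidean distance transform (EBImage watershed).
#'
#' @param mask a calibrated [binary_mask()].
#' @param tolerance minimum height (in distance-map pixels) of an object's
#'   seed maximum for it to be split out; guards against rasterization
#'   artifacts.
#' @return a [labeled_regions()] with label count >= connected-component
#'   count.
#' @export
watershed_split <- function(mask, tolerance = 1) {
  stopifnot(inherits(mask, "binary_mask"))
  px <- mask$pixels
  if (!any(px)) {
    return(labeled_regions(matrix(0L, nrow(px), ncol(px)), mask$calib_xy,
                           mask$calib_z,
                           provenance = c(mask$provenance,
                                          list(watershed = list(tolerance = tolerance)))))
  }
  dm <- EBImage::distmap(matrix(as.numeric(px), nrow(px)))
  w <- EBImage::watershed(dm, tolerance = tolerance)
  lab <- as.integer(round(EBImage::imageData(w)))
  dim(lab) <- dim(px)
  u <- sort(unique(lab[lab > 0L]))
  if (length(u) && !identical(u, seq_along(u))) lab <- relabel_keep(lab, u)
  labeled_regions(lab, mask$calib_xy, mask$calib_z,
                  provenance = c(mask$provenance,
                                 list(watershed = list(tolerance = tolerance))))
}

#' Label connected components
#'
#' Plain 8-connectivity component labeling of a binary mask (no splitting).
#'
#' @param mask a calibrated [binary_mask()].
#' @return a [labeled_regions()].
#' @export
label_mask <- function(mask) {
  stopifnot(inherits(mask, "binary_mask"))
  lab <- label_components(mask$pixels, 8L)
  labeled_regions(lab, mask$calib_xy, mask$calib_z,
                  provenance = c(mask$provenance, list(label = list(connectivity = 8))))
}

#' Measure labeled regions
#'
#' One record per positive label: calibrated area, summed intensity,
#' centroid (0-based row/col pixel coordinates), the semi-axes of the
#' second-moment equivalent ellipse (um) and the eccentricity
#' `sqrt(a^2 - b^2) / a`.  Pixels are treated as unit squares (a 1/12
#' moment correction), so even single-pixel objects have positive axes.
#'
#' @param labels a [labeled_regions()].
#' @param intensity an [image_channel()] of matching shape, or `NULL` to
#'   measure geometry only (sum intensity = pixel count).
#' @return a data.frame with columns `label`, `area_um2`, `sum_intensity`,
#'   `centroid_r`, `centroid_c`, `major_axis_a`, `minor_axis_b`,
#'   `eccentricity`.
#' @export
measure_regions <- function(labels, intensity = NULL) {
  stopifnot(inherits(labels, "labeled_regions"))
  lab <- labels$labels
  k <- max(lab, 0L)
  empty <- data.frame(label = integer(), area_um2 = numeric(),
                      sum_intensity = numeric(), centroid_r = numeric(),
                      centroid_c = numeric(), major_axis_a = numeric(),
                      minor_axis_b = numeric(), eccentricity = numeric())
  if (k == 0L) return(empty)
  if (!is.null(intensity)) {
    stopifnot(inherits(intensity, "image_channel"))
    if (!identical(dim(intensity$pixels), dim(lab)))
      stop("intensity shape does not match labels")
    ivals <- intensity$pixels
  } else {
    ivals <- array(1, dim(lab))
  }
  idx <- which(lab > 0L)
  l <- lab[idx]
  nr <- nrow(lab)
  r <- (idx - 1L) %% nr          # 0-based row
  cc <- (idx - 1L) %/% nr        # 0-based col
  n <- tabulate(l, k)
  sum_i <- as.numeric(rowsum(ivals[idx], l, reorder = TRUE))
  mr <- as.numeric(rowsum(r, l)) / n
  mc <- as.numeric(rowsum(cc, l)) / n
  # central second moments with the unit-square pixel correction
  mu_rr <- as.numeric(rowsum((r - mr[l])^2, l)) / n + 1 / 12
  mu_cc <- as.numeric(rowsum((cc - mc[l])^2, l)) / n + 1 / 12
  mu_rc <- as.numeric(rowsum((r - mr[l]) * (cc - mc[l]), l)) / n
  com <- sqrt(((mu_rr - mu_cc) / 2)^2 + mu_rc^2)
  l1 <- (mu_rr + mu_cc) / 2 + com
  l2 <- pmax((mu_rr + mu_cc) / 2 - com, 0)
  calib <- labels$calib_xy
  a <- 2 * sqrt(l1) * calib      # semi-axes of the equivalent ellipse, um
  b <- 2 * sqrt(l2) * calib
  data.frame(label = seq_len(k),
             area_um2 = n * calib^2,
             sum_intensity = sum_i,
             centroid_r = mr, centroid_c = mc,
             major_axis_a = a, minor_axis_b = b,
             eccentricity = ifelse(a > 0, sqrt(pmax(a^2 - b^2, 0)) / a, 0))
}
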