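## Nuclear shape analysis: segmentation, eccentricity, micronuclei, and the
## two-group K-means split of per-image mean nuclear areas.

#' Segment nuclei from a DAPI image
#'
#' Classical chain: [preprocess_nuclear()] enhancement, Otsu binarization,
#' removal of sub-`min_radius_um` debris and watershed splitting of touching
#' nuclei.  A pre-computed label raster can be passed through `labels` for
#' drop-in use of any external segmenter (e.g. a learned one); it is
#' returned unchanged.  `prob_threshold` and `overlap_threshold` are
#' recorded in provenance for parity with such segmenters but do not steer
#' the classical chain.
#'
#' @param dapi a 2D calibrated [image_channel()].
#' @param prob_threshold,overlap_threshold external-segmenter
#'   postprocessing parameters, recorded for provenance.
#' @param min_radius_um debris-removal radius in um; small enough by
#'   default (0.5 um) that micronuclei survive segmentation.
#' @param labels optional integer matrix of externally computed labels.
#' @return a [labeled_regions()] of nuclei.
#' @export
segment_nuclei <- function(dapi, prob_threshold = 0.5,
                           overlap_threshold = 0.6,
                           min_radius_um = 0.5, labels = NULL) {
  stopifnot(inherits(dapi, "image_channel"))
  prov <- list(segmenter = if (is.null(labels)) "classical" else "external",
               prob_threshold = prob_threshold,
               overlap_threshold = overlap_threshold)
  if (!is.null(labels)) {
    return(labeled_regions(labels, dapi$calib_xy, dapi$calib_z,
                           provenance = prov))
  }
  enh <- preprocess_nuclear(dapi)
  m <- auto_threshold(enh, "otsu")
  m <- remove_small_by_radius(m, min_radius_um)
  lab <- watershed_split(m)
  if (n_labels(lab) == 0L) stop("no nuclei")
  lab$provenance <- c(lab$provenance, prov)
  lab
}

#' Ellipse eccentricity from axis lengths
#'
#' `sqrt(a^2 - b^2) / a` with `a` the major and `b` the minor axis; 0 for a
#' circle, approaching 1 for elongated shapes.
#'
#' @param a major axis (um), `a >= b`.
#' @param b minor axis (um), `> 0`.
#' @return eccentricity in `[0, 1)`.
#' @examples
#' eccentricity_of(5, 3)   # 0.8
#' @export
eccentricity_of <- function(a, b) {
  if (any(b <= 0)) stop("axes must be positive")
  if (any(a < b)) stop("axis order")
  sqrt(a^2 - b^2) / a
}

#' Detect micronuclei among labeled DAPI objects
#'
#' Objects with area at most `small_area_max_um2` whose boundary lies within
#' `proximity_um` of a larger object are flagged as micronuclei, with the
#' nearest larger object as parent.  The ceiling and proximity defaults are
#' configuration choices (no quantitative definition exists in the
#' morphometry literature for cultured neurons); both are exposed.
#'
#' @param nuclei a [labeled_regions()].
#' @param small_area_max_um2 micronucleus area ceiling (um^2).
#' @param proximity_um maximum boundary-to-boundary distance to a parent.
#' @return data.frame of nucleus records: `label`, `area_um2`,
#'   `major_axis_a`, `minor_axis_b`, `eccentricity`, `is_micronucleus`,
#'   `parent_label` (NA for primaries and unflagged smalls).
#' @export
detect_micronuclei <- function(nuclei, small_area_max_um2 = 20,
                               proximity_um = 10) {
  stopifnot(inherits(nuclei, "labeled_regions"))
  meas <- measure_regions(nuclei)
  meas$is_micronucleus <- FALSE
  meas$parent_label <- NA_integer_
  if (!nrow(meas)) return(meas)
  small <- which(meas$area_um2 <= small_area_max_um2)
  big <- which(meas$area_um2 > small_area_max_um2)
  if (!length(small) || !length(big)) return(meas)
  lab <- nuclei$labels
  calib <- nuclei$calib_xy
  # distance from every pixel to the nearest large-object pixel
  big_px <- array(lab %in% meas$label[big], dim(lab))
  dm <- EBImage::distmap(matrix(as.numeric(!big_px), nrow(lab)))
  for (s in small) {
    idx <- which(lab == meas$label[s])
    dmin_px <- min(dm[idx])
    if (dmin_px * calib <= proximity_um) {
      meas$is_micronucleus[s] <- TRUE
      # parent = label of the nearest large pixel from the closest point
      p <- idx[which.min(dm[idx])]
      nr <- nrow(lab)
      pr <- (p - 1L) %% nr + 1L; pc <- (p - 1L) %/% nr + 1L
      r_px <- ceiling(dmin_px) + 2L
      rr <- max(1L, pr - r_px):min(nr, pr + r_px)
      cc <- max(1L, pc - r_px):min(ncol(lab), pc + r_px)
      sub <- lab[rr, cc, drop = FALSE]
      cand <- which(array(sub %in% meas$label[big], dim(sub)))
      if (length(cand)) {
        dr <- (cand - 1L) %% nrow(sub) + 1L
        dc <- (cand - 1L) %/% nrow(sub) + 1L
        dd <- (rr[dr] - pr)^2 + (cc[dc] - pc)^2
        meas$parent_label[s] <- sub[cand[which.min(dd)]]
      }
    }
  }
  meas
}

#' Two-group K-means split of per-image mean nuclear areas
#'
#' Exact 1-D 2-means: the global optimum of the within-cluster sum of
#' squares is attained at one of the `n - 1` contiguous splits of the
#' sorted values, all of which are scanned.  Deterministic and invariant
#' to input order and to positive rescaling of all areas.
#'
#' @param per_image_mean_areas numeric vector (um^2), `n >= 2`, at least two
#'   distinct values.
#' @return list with `assignment` (integer 1/2 per input value, cluster 1 =
#'   smaller center), `centers` (sorted ascending) and `withinss`.
#' @examples
#' kmeans_area_split(c(0.9, 1.0, 1.1, 9.8, 10.0, 10.5))
#' @export
kmeans_area_split <- function(per_image_mean_areas) {
  x <- per_image_mean_areas
  if (length(x) < 2) stop("need at least 2 values")
  if (any(!is.finite(x))) stop("values must be finite")
  if (length(unique(x)) < 2) stop("degenerate clustering")
  ord <- order(x)
  xs <- x[ord]
  n <- length(xs)
  css <- function(v) sum((v - mean(v))^2)
  best <- Inf; best_k <- 1L
  for (k in 1:(n - 1)) {
    w <- css(xs[1:k]) + css(xs[(k + 1):n])
    if (w < best - 1e-12) { best <- w; best_k <- k }
  }
  assignment <- integer(n)
  assignment[ord[1:best_k]] <- 1L
  assignment[ord[(best_k + 1):n]] <- 2L
  centers <- c(mean(xs[1:best_k]), mean(xs[(best_k + 1):n]))
  list(assignment = assignment, centers = centers, withinss = best)
}
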