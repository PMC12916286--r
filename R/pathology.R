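## The five per-image pathology quantification recipes, each a fixed
## operator chain over the image primitives.  Chains follow the
## interactive Fiji protocols step for step; every threshold and area gate is recorded
## in the result's qc block.

#' Build the MAP2 (neuronal area) mask for a recipe
#'
#' Recipe chains:
#' * `c9orf72`: Li threshold, remove particles < 2 um^2, fill holes 0-4 um^2.
#' * `tdp43`: CLAHE (blocksize 127, 256 bins, max slope 3.10), Otsu
#'   threshold, remove particles of equivalent radius < 5 um, fill holes
#'   0-4 um^2, watershed split (split labels stored in provenance).
#' * `p62`: Li threshold, remove particles of radius <= 5 um, watershed.
#'
#' @param map2 a 2D calibrated [image_channel()] (MAP2 staining).
#' @param recipe one of `"c9orf72"`, `"tdp43"`, `"p62"`.
#' @return a [binary_mask()]; when the chain ends in watershed the label
#'   raster is kept in `provenance$labels`.
#' @export
make_map2_mask <- function(map2, recipe = c("c9orf72", "tdp43", "p62")) {
  stopifnot(inherits(map2, "image_channel"))
  recipe <- match.arg(recipe)
  if (recipe == "c9orf72") {
    m <- auto_threshold(map2, "li")
    m <- remove_small_by_area(m, 2)
    m <- fill_holes_max_area(m, 4)
  } else if (recipe == "tdp43") {
    enh <- image_channel(nq_clahe(map2$pixels, blocksize = 127, nbins = 256,
                                  max_slope = 3.10),
                         map2$calib_xy, map2$calib_z, map2$role)
    m <- auto_threshold(enh, "otsu")
    m <- remove_small_by_radius(m, 5)
    m <- fill_holes_max_area(m, 4)
    lab <- watershed_split(m)
    m$provenance$labels <- lab$labels
    m$provenance$watershed <- lab$provenance$watershed
  } else {
    m <- auto_threshold(map2, "li")
    m <- remove_small_by_radius(m, 5, inclusive = TRUE)
    lab <- watershed_split(m)
    m$provenance$labels <- lab$labels
    m$provenance$watershed <- lab$provenance$watershed
  }
  m$provenance$recipe <- recipe
  m
}

#' Build the nuclear mask for a recipe
#'
#' Recipe chains:
#' * `c9orf72`: Otsu threshold, remove particles of radius < 5 um.
#' * `tdp43`: Renyi-entropy threshold, fill all enclosed holes.
#' * `gh2ax`: [preprocess_nuclear()] enhancement, Otsu binarization,
#'   remove particles of radius < 5 um; the total nuclear area is computed
#'   over regions of at least `gh2ax_min_area_um2` (1.5 um^2) and stored in
#'   `provenance$total_nuclear_area_um2`.
#'
#' @param dapi a 2D calibrated [image_channel()] (DAPI staining).
#' @param recipe one of `"c9orf72"`, `"tdp43"`, `"gh2ax"`.
#' @param gh2ax_min_area_um2 inclusion floor for the gh2ax total-area sum.
#' @return a [labeled_regions()] of nuclei.
#' @export
make_nuclear_mask <- function(dapi, recipe = c("c9orf72", "tdp43", "gh2ax"),
                              gh2ax_min_area_um2 = 1.5) {
  stopifnot(inherits(dapi, "image_channel"))
  recipe <- match.arg(recipe)
  if (recipe == "c9orf72") {
    m <- auto_threshold(dapi, "otsu")
    m <- remove_small_by_radius(m, 5)
    lab <- label_mask(m)
  } else if (recipe == "tdp43") {
    m <- auto_threshold(dapi, "renyi_entropy")
    m <- fill_holes_max_area(m, Inf)
    lab <- label_mask(m)
  } else {
    enh <- preprocess_nuclear(dapi)
    m <- auto_threshold(enh, "otsu")
    m <- remove_small_by_radius(m, 5)
    lab <- label_mask(m)
    meas <- measure_regions(lab)
    lab$provenance$total_nuclear_area_um2 <-
      sum(meas$area_um2[meas$area_um2 >= gh2ax_min_area_um2])
    lab$provenance$gh2ax_min_area_um2 <- gh2ax_min_area_um2
  }
  lab$provenance$recipe <- recipe
  lab
}

nq_assay_result <- function(image_id, assay, metrics, qc) {
  if (any(!is.finite(unlist(metrics)))) stop("metrics must be finite")
  structure(list(image_id = image_id, assay = assay,
                 metrics = metrics, qc = qc),
            class = "assay_result")
}

#' @export
print.assay_result <- function(x, ...) {
  cat(sprintf("<assay_result> %s  image=%s\n", x$assay, x$image_id))
  for (nm in names(x$metrics))
    cat(sprintf("  %-28s %g\n", nm, x$metrics[[nm]]))
  invisible(x)
}

#' C9orf72 somatodendritic intensity
#'
#' Sums the C9orf72 signal over the union of the MAP2-positive and
#' DAPI-positive (nuclear) areas and normalizes by the MAP2-positive area.
#'
#' @param map2,dapi,c9 co-registered 2D [image_channel()]s of equal shape.
#' @param image_id identifier recorded in the result.
#' @return an `assay_result` with metric `c9_sum_per_map2_area` (AU/um^2).
#' @export
c9orf72_intensity <- function(map2, dapi, c9, image_id = "image") {
  stopifnot(identical(dim(map2$pixels), dim(c9$pixels)),
            identical(dim(dapi$pixels), dim(c9$pixels)))
  mm <- make_map2_mask(map2, "c9orf72")
  if (!any(mm$pixels)) stop("no neuronal area")
  nl <- make_nuclear_mask(dapi, "c9orf72")
  union_px <- mm$pixels | (nl$labels > 0L)
  calib2 <- map2$calib_xy^2
  map2_area <- sum(mm$pixels) * calib2
  s <- sum(c9$pixels[union_px])
  nq_assay_result(image_id, "c9orf72",
                  metrics = list(c9_sum_per_map2_area = s / map2_area),
                  qc = list(map2_area_um2 = map2_area,
                            union_area_um2 = sum(union_px) * calib2,
                            n_nuclei = n_labels(nl),
                            map2_threshold = mm$provenance$threshold))
}

#' TDP-43 cytosol-to-nucleus intensity ratio
#'
#' Per image: builds the MAP2 cell-body mask (tdp43 recipe) and the nuclear
#' labels (Renyi + fill holes), keeps only nuclei whose centroid lies inside
#' the MAP2 mask, and computes
#' `ratio = [(S_cell - S_nuc) / (A_cell - A_nuc)] / [S_nuc / A_nuc]`
#' where S are TDP-43 sum intensities and A areas of the cell-body and
#' retained-nuclei compartments.
#'
#' @param map2,dapi,tdp43 co-registered 2D [image_channel()]s.
#' @param image_id identifier recorded in the result.
#' @return an `assay_result` with metric `cyto_nuclear_ratio`; qc holds all
#'   four terms.
#' @export
tdp43_cyto_nuclear_ratio <- function(map2, dapi, tdp43, image_id = "image") {
  stopifnot(identical(dim(map2$pixels), dim(tdp43$pixels)),
            identical(dim(dapi$pixels), dim(tdp43$pixels)))
  mm <- make_map2_mask(map2, "tdp43")
  if (!any(mm$pixels)) stop("no neuronal area")
  nl <- make_nuclear_mask(dapi, "tdp43")
  if (n_labels(nl) == 0L) stop("no nuclei")
  meas <- measure_regions(nl)
  # nucleus retained iff its centroid lies in the MAP2 mask
  cen_r <- pmin(pmax(round(meas$centroid_r) + 1L, 1L), nrow(mm$pixels))
  cen_c <- pmin(pmax(round(meas$centroid_c) + 1L, 1L), ncol(mm$pixels))
  keep <- meas$label[mm$pixels[cbind(cen_r, cen_c)]]
  if (!length(keep)) stop("no nuclei")
  nuc_px <- nl$labels > 0L & array(nl$labels %in% keep, dim(nl$labels))
  calib2 <- map2$calib_xy^2
  a_cell <- sum(mm$pixels) * calib2
  a_nuc <- sum(nuc_px) * calib2
  s_cell <- sum(tdp43$pixels[mm$pixels])
  s_nuc <- sum(tdp43$pixels[nuc_px])
  if (a_cell <= a_nuc) stop("no cytosolic area")
  if (s_nuc <= 0) stop("zero nuclear signal")
  cyto_density <- (s_cell - s_nuc) / (a_cell - a_nuc)
  nuc_density <- s_nuc / a_nuc
  nq_assay_result(image_id, "tdp43_ratio",
                  metrics = list(cyto_nuclear_ratio =
                                   max(cyto_density, 0) / nuc_density),
                  qc = list(S_cell = s_cell, S_nuc = s_nuc,
                            A_cell_um2 = a_cell, A_nuc_um2 = a_nuc,
                            n_nuclei_retained = length(keep),
                            n_nuclei_total = n_labels(nl)))
}

#' p62/SQSTM1 vesicle metrics
#'
#' Detects p62-positive vesicles within MAP2-positive regions: the p62
#' channel is binarized with the Renyi-entropy threshold, restricted to the
#' MAP2 mask (p62 recipe), and only particles within the admission window
#' `[0.01, 1]` um^2 are counted.
#'
#' @param map2,p62 co-registered 2D [image_channel()]s.
#' @param admission_um2 vesicle area admission window (um^2).
#' @param image_id identifier recorded in the result.
#' @return an `assay_result` with metrics `count_per_map2_area` (um^-2),
#'   `mean_vesicle_area` (um^2) and `mean_integrated_density` (AU).
#' @export
p62_vesicle_metrics <- function(map2, p62, admission_um2 = c(0.01, 1),
                                image_id = "image") {
  stopifnot(identical(dim(map2$pixels), dim(p62$pixels)))
  mm <- make_map2_mask(map2, "p62")
  if (!any(mm$pixels)) stop("no neuronal area")
  map2_area <- sum(mm$pixels) * map2$calib_xy^2
  if (max(p62$pixels) <= min(p62$pixels)) {
    # flat channel: no vesicles
    return(nq_assay_result(image_id, "p62",
                           metrics = list(count_per_map2_area = 0,
                                          mean_vesicle_area = 0,
                                          mean_integrated_density = 0),
                           qc = list(map2_area_um2 = map2_area,
                                     n_vesicles = 0L,
                                     admission_um2 = admission_um2)))
  }
  # threshold computed on the MAP2-positive signal only
  tw <- nq_threshold_within(p62$pixels, mm$pixels, "renyi_entropy")
  vb <- binary_mask(tw$pixels, p62$calib_xy,
                    provenance = list(threshold = tw$threshold))
  lab <- label_mask(vb)
  meas <- measure_regions(lab, p62)
  adm <- meas$area_um2 >= admission_um2[1] & meas$area_um2 <= admission_um2[2]
  meas <- meas[adm, , drop = FALSE]
  n <- nrow(meas)
  nq_assay_result(image_id, "p62",
                  metrics = list(
                    count_per_map2_area = n / map2_area,
                    mean_vesicle_area = if (n) mean(meas$area_um2) else 0,
                    mean_integrated_density = if (n) mean(meas$sum_intensity)
                                              else 0),
                  qc = list(map2_area_um2 = map2_area, n_vesicles = n,
                            admission_um2 = admission_um2,
                            p62_threshold = vb$provenance$threshold))
}

#' gamma-H2A.X DNA-damage foci metrics
#'
#' Removes any gamma-H2A.X signal outside the DAPI nuclear mask (gh2ax
#' recipe), normalizes the remaining sum intensity by the total nuclear
#' area, then binarizes the masked signal with the max-entropy threshold
#' and counts particles with area above `min_focus_area_um2`.
#'
#' @param dapi,gh2ax co-registered 2D [image_channel()]s.
#' @param min_focus_area_um2 focus admission floor (um^2).
#' @param image_id identifier recorded in the result.
#' @return an `assay_result` with metrics `sum_intensity_per_nuclear_area`,
#'   `foci_count_per_nuclear_area` and `mean_focus_area`.
#' @export
gh2ax_metrics <- function(dapi, gh2ax, min_focus_area_um2 = 0.00001,
                          image_id = "image") {
  stopifnot(identical(dim(dapi$pixels), dim(gh2ax$pixels)))
  nl <- make_nuclear_mask(dapi, "gh2ax")
  if (n_labels(nl) == 0L) stop("no nuclei")
  area <- nl$provenance$total_nuclear_area_um2
  if (is.null(area) || area <= 0) stop("no nuclei")
  g <- gh2ax$pixels
  g[nl$labels == 0L] <- 0
  s <- sum(g)
  if (max(g) <= min(g)) {
    # flat (e.g. all-zero) channel: no foci
    return(nq_assay_result(image_id, "gh2ax",
                           metrics = list(sum_intensity_per_nuclear_area = s / area,
                                          foci_count_per_nuclear_area = 0,
                                          mean_focus_area = 0),
                           qc = list(total_nuclear_area_um2 = area,
                                     n_nuclei = n_labels(nl), n_foci = 0)))
  }
  gi <- image_channel(g, gh2ax$calib_xy, role = gh2ax$role)
  # threshold computed on the remaining (in-nucleus) signal only
  tw <- nq_threshold_within(g, nl$labels > 0L, "max_entropy")
  fb <- binary_mask(tw$pixels, gh2ax$calib_xy,
                    provenance = list(threshold = tw$threshold))
  lab <- label_mask(fb)
  meas <- measure_regions(lab, gi)
  meas <- meas[meas$area_um2 > min_focus_area_um2, , drop = FALSE]
  n <- nrow(meas)
  nq_assay_result(image_id, "gh2ax",
                  metrics = list(
                    sum_intensity_per_nuclear_area = s / area,
                    foci_count_per_nuclear_area = n / area,
                    mean_focus_area = if (n) mean(meas$area_um2) else 0),
                  qc = list(total_nuclear_area_um2 = area,
                            n_nuclei = n_labels(nl), n_foci = n,
                            foci_threshold = fb$provenance$threshold))
}

#' RNA-FISH foci per nucleus
#'
#' Segments nuclei with [make_nuclear_mask()] and counts FISH puncta
#' (max-entropy threshold, admission window `admission_um2`) whose centroid
#' lies inside each nucleus.  A focus straddling two nuclei is assigned to
#' the nucleus containing its centroid and counted once.
#'
#' @param dapi,fish co-registered 2D [image_channel()]s.
#' @param recipe nuclear-mask recipe (default `"c9orf72"`: Otsu + >= 5 um
#'   radius).
#' @param admission_um2 punctum area admission window (um^2).
#' @return a `foci_table` data.frame: one row per retained nucleus with
#'   columns `nucleus` and `foci_count`.
#' @export
rna_foci_per_nucleus <- function(dapi, fish, recipe = "c9orf72",
                                 admission_um2 = c(0.05, 2)) {
  stopifnot(identical(dim(dapi$pixels), dim(fish$pixels)))
  nl <- make_nuclear_mask(dapi, recipe)
  k <- n_labels(nl)
  out <- data.frame(nucleus = seq_len(k), foci_count = 0L)
  class(out) <- c("foci_table", "data.frame")
  if (k == 0L) return(out)
  if (max(fish$pixels) <= min(fish$pixels)) return(out)
  fb <- auto_threshold(fish, "max_entropy")
  lab <- label_mask(fb)
  meas <- measure_regions(lab, fish)
  meas <- meas[meas$area_um2 >= admission_um2[1] &
                 meas$area_um2 <= admission_um2[2], , drop = FALSE]
  if (nrow(meas)) {
    cen_r <- pmin(pmax(round(meas$centroid_r) + 1L, 1L), nrow(nl$labels))
    cen_c <- pmin(pmax(round(meas$centroid_c) + 1L, 1L), ncol(nl$labels))
    owner <- nl$labels[cbind(cen_r, cen_c)]
    tab <- table(owner[owner > 0L])
    out$foci_count[as.integer(names(tab))] <- as.integer(tab)
  }
  out
}

#' Summarize an RNA-foci table
#'
#' @param table a data.frame with column `foci_count`, one row per nucleus.
#' @return list with `fraction_positive` (percent of nuclei with at least
#'   one focus), `mean_foci_positive` (mean count over positive nuclei;
#'   `NA` when none) and `range` (min/max over positive nuclei).
#' @examples
#' foci_summary(data.frame(foci_count = c(0, 0, 0, 1, 2, 3)))
#' @export
foci_summary <- function(table) {
  if (!is.data.frame(table) || !nrow(table)) stop("empty table")
  cnt <- table$foci_count
  if (any(cnt < 0) || any(cnt != round(cnt))) stop("counts must be non-negative integers")
  pos <- cnt[cnt > 0]
  list(fraction_positive = 100 * length(pos) / length(cnt),
       mean_foci_positive = if (length(pos)) mean(pos) else NA_real_,
       range = if (length(pos)) range(pos) else c(NA_real_, NA_real_))
}
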