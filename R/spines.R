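## Dendritic spine detection and mushroom/stubby/thin classification on
## calibrated 3D stacks, with the standard NeuronStudio parameter set.

#' Spine classifier parameters
#'
#' Defaults are the conventional NeuronStudio settings: head/neck ratio 1.1,
#' thin (length/head) ratio 2.5, mushroom head size 0.35 um, spine height
#' 0.2-5.0 um, maximum width 3 um, voxel-count gates of 10 (maximum stubby
#' size) and 5 (minimum non-stubby size) at the reference voxel size
#' 0.066 x 0.066 x 0.390 um.
#'
#' @param neck_ratio minimum head/neck diameter ratio for a neck to count.
#' @param thin_ratio minimum length/head ratio for a thin spine.
#' @param mushroom_size_um minimum head diameter of a mushroom spine (um).
#' @param min_height_um,max_height_um admissible spine height range (um).
#' @param max_width_um maximum admissible spine width (um).
#' @param max_stubby_voxels,min_non_stubby_voxels voxel-count gates at the
#'   reference voxel size.
#' @param ref_voxel_um reference voxel size for the voxel-count gates.
#' @return a named list of class `spine_params`.
#' @export
spine_params <- function(neck_ratio = 1.1, thin_ratio = 2.5,
                         mushroom_size_um = 0.35,
                         min_height_um = 0.2, max_height_um = 5.0,
                         max_width_um = 3,
                         max_stubby_voxels = 10, min_non_stubby_voxels = 5,
                         ref_voxel_um = c(0.066, 0.066, 0.390)) {
  p <- list(neck_ratio = neck_ratio, thin_ratio = thin_ratio,
            mushroom_size_um = mushroom_size_um,
            min_height_um = min_height_um, max_height_um = max_height_um,
            max_width_um = max_width_um,
            max_stubby_voxels = max_stubby_voxels,
            min_non_stubby_voxels = min_non_stubby_voxels,
            ref_voxel_um = ref_voxel_um)
  if (p$min_height_um >= p$max_height_um) stop("min_height must be < max_height")
  if (any(unlist(p) <= 0)) stop("all parameters must be positive")
  class(p) <- "spine_params"
  p
}

#' Classify one spine from its geometry
#'
#' Decision tree at the standard thresholds:
#' 1. a neck exists iff `neck_diameter` is present and
#'    `head_diameter / neck_diameter >= neck_ratio`;
#' 2. if a neck exists and `head_diameter >= mushroom_size_um` the spine is
#'    a mushroom;
#' 3. otherwise, if `length / head_diameter >= thin_ratio` it is thin;
#' 4. otherwise it is stubby.
#' All comparisons use `>=` (a head of exactly 0.35 um is mushroom).
#'
#' @param head_diameter head diameter in um (> 0).
#' @param length spine length (base to tip) in um (> 0).
#' @param neck_diameter neck diameter in um, or `NA`/`NULL` when absent.
#' @param params a [spine_params()].
#' @return one of `"mushroom"`, `"thin"`, `"stubby"`.
#' @examples
#' classify_spine(0.5, 1.0, 0.2)   # mushroom
#' classify_spine(0.25, 1.0, 0.2)  # thin (length/head = 4)
#' @export
classify_spine <- function(head_diameter, length, neck_diameter = NA,
                           params = spine_params()) {
  if (is.null(neck_diameter)) neck_diameter <- NA_real_
  if (head_diameter <= 0 || length <= 0 ||
      (!is.na(neck_diameter) && neck_diameter <= 0))
    stop("non-positive geometry")
  neck_exists <- !is.na(neck_diameter) &&
    head_diameter / neck_diameter >= params$neck_ratio
  if (neck_exists && head_diameter >= params$mushroom_size_um)
    return("mushroom")
  if (length / head_diameter >= params$thin_ratio) return("thin")
  "stubby"
}

#' Detect dendritic spines in a calibrated 3D stack
#'
#' A simplified volumetric detector: the stack is binarized (Otsu), the
#' largest connected component is taken as the dendrite, its shaft axis is
#' estimated by principal components of the voxel cloud and its radius by a
#' robust per-slab median, and protrusions are the connected clusters of
#' voxels beyond the shaft surface.  Per protrusion, cross-section
#' diameters are measured along the protrusion axis (extent along the
#' well-sampled shaft direction): the head diameter is the widest
#' cross-section of the distal third, the neck the narrowest cross-section
#' between base and head (reported only when head/neck >= `neck_ratio`).
#' Protrusions outside the height window `[min_height_um, max_height_um]`
#' or wider than `max_width_um` are rejected.
#'
#' @param stack a 3D [image_channel()] with `calib_xy` and `calib_z`.
#' @param params a [spine_params()].
#' @return data.frame of admitted spine geometries (`position_um`,
#'   `length`, `head_diameter`, `neck_diameter`, `max_width`,
#'   `voxel_count_ref`, `spine_class`), with attributes
#'   `dendrite_length_um` and `shaft_radius_um`.
#' @export
detect_spines <- function(stack, params = spine_params()) {
  stopifnot(inherits(stack, "image_channel"))
  if (length(dim(stack$pixels)) != 3L) stop("stack must be 3D")
  vx <- stack$calib_xy; vz <- stack$calib_z
  d <- dim(stack$pixels)
  if (max(stack$pixels) <= min(stack$pixels)) stop("no dendrite")
  h <- nq_hist256(stack$pixels)
  fg <- h$bins > nq_thr_otsu(h)
  dim(fg) <- d
  lab <- label_components(fg, 26L)
  k <- max(lab, 0L)
  if (k == 0L) stop("no dendrite")
  sizes <- tabulate(lab[lab > 0L], k)
  main <- which.max(sizes)
  if (sizes[main] < 200L) stop("no dendrite")
  idx <- which(lab == main)
  ix <- (idx - 1L) %% d[1] + 1L
  rem <- (idx - 1L) %/% d[1]
  iy <- rem %% d[2] + 1L
  iz <- rem %/% d[2] + 1L
  P <- cbind((ix - 0.5) * vx, (iy - 0.5) * vx, (iz - 0.5) * vz)  # um
  ctr <- colMeans(P)
  pc <- eigen(stats::cov(P), symmetric = TRUE)
  v <- pc$vectors[, 1]                 # shaft direction
  w1 <- pc$vectors[, 2]; w2 <- pc$vectors[, 3]
  s <- (P[, 1] - ctr[1]) * v[1] + (P[, 2] - ctr[2]) * v[2] +
       (P[, 3] - ctr[3]) * v[3]
  u1 <- (P[, 1] - ctr[1]) * w1[1] + (P[, 2] - ctr[2]) * w1[2] +
        (P[, 3] - ctr[3]) * w1[3]
  u2 <- (P[, 1] - ctr[1]) * w2[1] + (P[, 2] - ctr[2]) * w2[2] +
        (P[, 3] - ctr[3]) * w2[3]
  dendrite_length <- diff(range(s))
  # per-slab robust centerline and radius
  slab_w <- max(4 * vx, 0.25)
  slab <- floor((s - min(s)) / slab_w) + 1L
  slab_of <- as.character(slab)
  c1 <- tapply(u1, slab, stats::median)
  c2 <- tapply(u2, slab, stats::median)
  rad <- sqrt((u1 - c1[slab_of])^2 + (u2 - c2[slab_of])^2)
  shaft_r <- stats::median(tapply(rad, slab, stats::median)) * sqrt(2)
  # refine: large protrusions bias a slab's median center toward
  # themselves; recompute the centerline from core (shaft-radius) voxels
  for (pass in 1:2) {
    core <- rad <= shaft_r * 1.05
    c1n <- tapply(u1[core], slab[core], stats::median)
    c2n <- tapply(u2[core], slab[core], stats::median)
    c1[names(c1n)] <- c1n; c2[names(c2n)] <- c2n
    rad <- sqrt((u1 - c1[slab_of])^2 + (u2 - c2[slab_of])^2)
    shaft_r <- stats::median(tapply(rad[core], slab[core],
                                    stats::median)) * sqrt(2)
  }
  margin <- max(1.5 * vx, 0.1)
  spine_sel <- rad > shaft_r + margin
  if (!any(spine_sel)) {
    out <- nq_empty_spines()
    attr(out, "dendrite_length_um") <- dendrite_length
    attr(out, "shaft_radius_um") <- shaft_r
    return(out)
  }
  spx <- array(FALSE, d)
  spx[idx[spine_sel]] <- TRUE
  slab_lab <- label_components(spx, 26L)
  nsp <- max(slab_lab, 0L)
  rows <- list()
  vol_ratio <- (vx * vx * vz) /
    (params$ref_voxel_um[1] * params$ref_voxel_um[2] * params$ref_voxel_um[3])
  for (sp in seq_len(nsp)) {
    sel <- which(slab_lab[idx] == sp)
    if (length(sel) < 3L) next
    rs <- rad[sel]; ss <- s[sel]
    len <- max(rs) - shaft_r + 0.5 * vx
    # axial coordinate: radial distance beyond the shaft surface.  Shells
    # of constant radius approximate cross-sections perpendicular to a
    # radially protruding spine and are robust to cap/rim corners.
    t_ax <- rs - shaft_r
    bins <- floor(t_ax / vx)
    # diameter per cross-section: extent along the shaft direction
    ext <- tapply(ss, bins, function(z) diff(range(z)) + vx)
    tb <- as.numeric(names(ext))
    keep_b <- tb >= 0
    if (!any(keep_b)) next
    ext <- ext[keep_b]; tb <- tb[keep_b]
    distal <- tb * vx >= (2 / 3) * len
    head_d <- if (any(distal)) max(ext[distal]) else max(ext)
    head_at <- tb[which(ext == head_d & (if (any(distal)) distal else TRUE))[1]]
    proximal <- tb * vx >= 0.05 * len & tb < head_at
    neck_d <- if (any(proximal)) min(ext[proximal]) else NA_real_
    max_w <- max(ext)
    if (len < params$min_height_um || len > params$max_height_um) next
    if (max_w > params$max_width_um) next
    nvox_ref <- length(sel) * vol_ratio
    neck_rep <- if (!is.na(neck_d) && head_d / neck_d >= params$neck_ratio)
      neck_d else NA_real_
    cls <- if (nvox_ref < params$min_non_stubby_voxels) "stubby"
           else classify_spine(head_d, len, neck_rep, params)
    rows[[length(rows) + 1L]] <-
      data.frame(position_um = stats::median(ss) - min(s),
                 length = len, head_diameter = head_d,
                 neck_diameter = neck_rep, max_width = max_w,
                 voxel_count_ref = nvox_ref, spine_class = cls)
  }
  out <- if (length(rows)) do.call(rbind, rows) else nq_empty_spines()
  out <- out[order(out$position_um), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "dendrite_length_um") <- dendrite_length
  attr(out, "shaft_radius_um") <- shaft_r
  out
}

nq_empty_spines <- function() {
  data.frame(position_um = numeric(), length = numeric(),
             head_diameter = numeric(), neck_diameter = numeric(),
             max_width = numeric(), voxel_count_ref = numeric(),
             spine_class = character())
}

#' Summarize detected spines on one dendrite
#'
#' @param spines data.frame as returned by [detect_spines()] (needs columns
#'   `spine_class` and `head_diameter`).
#' @param dendrite_length_um dendrite length in um (> 0).
#' @return list with `density_per_um`, `type_fractions` (percent, summing
#'   to 100 for nonempty input) and `mean_head_diameter_by_type`.
#' @export
spine_summary <- function(spines, dendrite_length_um) {
  if (dendrite_length_um <= 0) stop("dendrite_length must be positive")
  n <- nrow(spines)
  if (n == 0L) {
    return(list(density_per_um = 0, type_fractions = NULL,
                mean_head_diameter_by_type = NULL))
  }
  classes <- c("mushroom", "stubby", "thin")
  cnt <- table(factor(spines$spine_class, levels = classes))
  tf <- 100 * as.numeric(cnt) / n
  names(tf) <- classes
  list(density_per_um = n / dendrite_length_um,
       type_fractions = tf,
       mean_head_diameter_by_type =
         tapply(spines$head_diameter, factor(spines$spine_class,
                                             levels = classes), mean))
}
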