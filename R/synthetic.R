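## Ground-truth fixture generators.
##
## Every generator is a pure function of its arguments including the seed:
## the RNG state of the caller is saved and restored, and the same seed
## reproduces the output bit for bit.  Each generator returns both the data
## and a manifest recording every planted object, so round-trip tests can
## compare recovered metrics against known truth.

nq_with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else suppressWarnings(rm(".Random.seed", envir = globalenv()))
  })
  set.seed(seed)
  force(code)
}

## anti-aliased disk: coverage ramps over `edge` pixels at the rim (the
## half-coverage contour sits exactly at r_px, so thresholding at half the
## object intensity recovers the planted area; small puncta use a narrow
## edge so the rim contributes little area at any reasonable threshold)
nq_draw_disk <- function(img, cy, cx, r_px, intensity, add = TRUE,
                         edge = 1) {
  nr <- nrow(img); nc <- ncol(img)
  r0 <- max(1L, floor(cy - r_px - 2)); r1 <- min(nr, ceiling(cy + r_px + 2))
  c0 <- max(1L, floor(cx - r_px - 2)); c1 <- min(nc, ceiling(cx + r_px + 2))
  if (r0 > r1 || c0 > c1) return(img)
  rr <- r0:r1; cc <- c0:c1
  d <- sqrt(outer((rr - cy)^2, (cc - cx)^2, "+"))
  cov <- pmin(pmax((r_px - d) / edge + 0.5, 0), 1)
  patch <- img[rr, cc, drop = FALSE]
  img[rr, cc] <- if (add) patch + intensity * cov
                 else pmax(patch, intensity * cov)
  img
}

## anti-aliased filled ellipse with semi-axes a >= b (px) rotated by theta
nq_draw_ellipse <- function(img, cy, cx, a_px, b_px, theta, intensity,
                            add = TRUE) {
  nr <- nrow(img); nc <- ncol(img)
  ext <- a_px + 2
  r0 <- max(1L, floor(cy - ext)); r1 <- min(nr, ceiling(cy + ext))
  c0 <- max(1L, floor(cx - ext)); c1 <- min(nc, ceiling(cx + ext))
  rr <- r0:r1; cc <- c0:c1
  dy <- matrix(rr - cy, length(rr), length(cc))
  dx <- matrix(cc - cx, length(rr), length(cc), byrow = TRUE)
  u <- sqrt(((dy * cos(theta) + dx * sin(theta)) / a_px)^2 +
              ((-dy * sin(theta) + dx * cos(theta)) / b_px)^2)
  cov <- pmin(pmax((1 - u) * b_px + 0.5, 0), 1)
  patch <- img[rr, cc, drop = FALSE]
  img[rr, cc] <- if (add) patch + intensity * cov
                 else pmax(patch, intensity * cov)
  img
}

nq_place_nonoverlap <- function(n, nr, nc, radius_px, margin_px = 4,
                                max_restarts = 50, tries_per_restart = 400) {
  for (restart in seq_len(max_restarts)) {
    pts <- matrix(NA_real_, n, 2)
    placed <- 0L
    for (try in seq_len(tries_per_restart)) {
      cy <- runif(1, radius_px + margin_px, nr - radius_px - margin_px)
      cx <- runif(1, radius_px + margin_px, nc - radius_px - margin_px)
      if (placed == 0L ||
          all(sqrt((pts[seq_len(placed), 1] - cy)^2 +
                   (pts[seq_len(placed), 2] - cx)^2) >
              2 * radius_px + margin_px)) {
        placed <- placed + 1L
        pts[placed, ] <- c(cy, cx)
        if (placed == n) return(pts)
      }
    }
  }
  stop("could not place objects without overlap")
}

nq_apply_noise <- function(img, poisson_snr = NULL, snr_ref_intensity = NULL,
                           gaussian_sd = 0, psf_sigma_px = 0.9) {
  noisy <- FALSE
  if (!is.null(poisson_snr)) {
    iref <- snr_ref_intensity %||% max(img)
    if (iref <= 0) stop("snr reference intensity must be positive")
    cfac <- poisson_snr^2 / iref      # photons per AU so that SNR(iref) = snr
    img[] <- stats::rpois(length(img), pmax(img, 0) * cfac) / cfac
    noisy <- TRUE
  }
  if (gaussian_sd > 0) {
    img[] <- pmax(img + stats::rnorm(length(img), 0, gaussian_sd), 0)
    noisy <- TRUE
  }
  # processed confocal (Airyscan-style) output has spatially correlated
  # noise: apply the instrument's effective PSF after noise injection
  if (noisy && psf_sigma_px > 0)
    img <- EBImage::gblur(img, sigma = psf_sigma_px)
  pmax(img, 0)
}

#' Generate a synthetic immunofluorescence image set
#'
#' Draws anti-aliased somata (MAP2 channel), elliptical nuclei (DAPI
#' channel), optional micronuclei, and one assay channel according to the
#' requested plan; returns calibrated channels plus a ground-truth manifest.
#' Defaults emulate confocal fields of cultured neurons: a 512 x 512 frame
#' at 0.1 um/px, three somata of 12 um radius and one nucleus per soma with
#' semi-axes within 5-7.5 um.
#'
#' Assay plans (`assay$type`):
#' * `"tdp43"`: uniform nuclear intensity `nuclear_intensity` inside nuclei
#'   and `cyto_ratio * nuclear_intensity` in the rest of the soma.
#' * `"c9orf72"`: uniform intensity `intensity` over soma and nucleus.
#' * `"p62"`: `n_puncta` puncta of `punctum_area_um2` at `intensity`
#'   planted inside somata.
#' * `"gh2ax"`: `foci_per_nucleus` foci of `focus_area_um2` at `intensity`
#'   inside each nucleus.
#' * `"fish"`: per-nucleus foci counts from `foci_counts`.
#'
#' @param seed integer RNG seed; fully determines the output.
#' @param shape image size `c(rows, cols)` in px.
#' @param calib_xy um per pixel.
#' @param n_somata number of somata.
#' @param soma_radius_um soma radius in um.
#' @param soma_intensity MAP2 intensity inside somata.
#' @param nucleus_a_um,nucleus_b_um ranges (length-2) for the nuclear
#'   semi-axes in um; each nucleus samples uniformly within them.
#' @param dapi_intensity DAPI intensity inside nuclei.
#' @param n_micronuclei number of micronuclei (planted next to nuclei).
#' @param micronucleus_area_um2 micronucleus area in um^2.
#' @param micronucleus_gap_um gap between micronucleus and parent boundary.
#' @param background constant background level added to all channels.
#' @param assay assay plan list (see Details) or `NULL` for no assay channel.
#' @param noise list with optional `poisson_snr` (shot-noise SNR at the
#'   brightest planted intensity), `gaussian_sd` (read noise, AU) and
#'   `psf_sigma_px` (effective PSF of the processed output, default 0.9 px;
#'   applied after noise injection so the noise is spatially correlated, as
#'   in Airyscan-style processed confocal data).
#' @return list with elements `dapi`, `map2`, `assay` ([image_channel()]s;
#'   `assay` may be `NULL`) and `manifest`.
#' @export
gen_if_image <- function(seed, shape = c(512L, 512L), calib_xy = 0.1,
                         n_somata = 3, soma_radius_um = 12,
                         soma_intensity = 150,
                         nucleus_a_um = c(6, 7.5), nucleus_b_um = c(5, 6),
                         dapi_intensity = 180,
                         n_micronuclei = 0, micronucleus_area_um2 = 5,
                         micronucleus_gap_um = 2,
                         background = 5, assay = NULL,
                         noise = list()) {
  nq_with_seed(seed, {
    nr <- shape[1]; nc <- shape[2]
    soma_r_px <- soma_radius_um / calib_xy
    dapi <- matrix(0, nr, nc); map2 <- matrix(0, nr, nc)
    asy <- matrix(0, nr, nc)
    pts <- nq_place_nonoverlap(n_somata, nr, nc, soma_r_px)
    somata <- data.frame(id = seq_len(n_somata), cy = pts[, 1], cx = pts[, 2],
                         radius_um = soma_radius_um,
                         intensity = soma_intensity)
    for (i in seq_len(n_somata))
      map2 <- nq_draw_disk(map2, pts[i, 1], pts[i, 2], soma_r_px,
                           soma_intensity, add = FALSE)
    nuclei <- data.frame(id = seq_len(n_somata), cy = NA_real_, cx = NA_real_,
                         a_um = NA_real_, b_um = NA_real_, theta = NA_real_,
                         area_um2 = NA_real_, soma = seq_len(n_somata))
    for (i in seq_len(n_somata)) {
      a <- runif(1, nucleus_a_um[1], nucleus_a_um[2])
      b <- runif(1, nucleus_b_um[1], nucleus_b_um[2])
      th <- runif(1, 0, pi)
      # keep the nucleus inside the soma with room to spare
      maxoff <- (soma_radius_um - a - 1) / calib_xy
      ang <- runif(1, 0, 2 * pi); off <- runif(1, 0, max(maxoff, 0))
      cy <- pts[i, 1] + off * sin(ang); cx <- pts[i, 2] + off * cos(ang)
      dapi <- nq_draw_ellipse(dapi, cy, cx, a / calib_xy, b / calib_xy, th,
                              dapi_intensity, add = FALSE)
      nuclei[i, c("cy", "cx", "a_um", "b_um", "theta", "area_um2")] <-
        c(cy, cx, a, b, th, pi * a * b)
    }
    micronuclei <- NULL
    if (n_micronuclei > 0) {
      mn_r_um <- sqrt(micronucleus_area_um2 / pi)
      micronuclei <- data.frame(id = seq_len(n_micronuclei),
                                parent = rep(seq_len(n_somata),
                                             length.out = n_micronuclei),
                                cy = NA_real_, cx = NA_real_,
                                area_um2 = micronucleus_area_um2)
      for (j in seq_len(n_micronuclei)) {
        i <- micronuclei$parent[j]
        ang <- runif(1, 0, 2 * pi)
        # place beyond the parent's major axis so the gap is guaranteed
        dist_um <- nuclei$a_um[i] + micronucleus_gap_um + mn_r_um
        cy <- nuclei$cy[i] + dist_um / calib_xy * sin(ang)
        cx <- nuclei$cx[i] + dist_um / calib_xy * cos(ang)
        cy <- min(max(cy, mn_r_um / calib_xy + 2), nr - mn_r_um / calib_xy - 2)
        cx <- min(max(cx, mn_r_um / calib_xy + 2), nc - mn_r_um / calib_xy - 2)
        dapi <- nq_draw_disk(dapi, cy, cx, mn_r_um / calib_xy,
                             dapi_intensity, add = FALSE)
        micronuclei[j, c("cy", "cx")] <- c(cy, cx)
      }
    }
    assay_manifest <- NULL
    peak_intensity <- max(soma_intensity, dapi_intensity)
    if (!is.null(assay)) {
      type <- assay$type
      if (type == "tdp43") {
        nuc_i <- assay$nuclear_intensity %||% 200
        ratio <- assay$cyto_ratio %||% 0.5
        nuc_mask <- dapi > dapi_intensity / 2
        cell_mask <- map2 > soma_intensity / 2
        asy[cell_mask] <- nuc_i * ratio
        asy[nuc_mask] <- nuc_i
        assay_manifest <- list(type = type, nuclear_intensity = nuc_i,
                               cyto_ratio = ratio)
        peak_intensity <- max(peak_intensity, nuc_i)
      } else if (type == "c9orf72") {
        ii <- assay$intensity %||% 120
        asy[map2 > soma_intensity / 2 | dapi > dapi_intensity / 2] <- ii
        assay_manifest <- list(type = type, intensity = ii)
        peak_intensity <- max(peak_intensity, ii)
      } else if (type == "p62") {
        np <- assay$n_puncta %||% 15
        pa <- assay$punctum_area_um2 %||% 0.25
        ii <- assay$intensity %||% 120
        pr <- sqrt(pa / pi) / calib_xy
        pd <- data.frame(id = seq_len(np), cy = NA_real_, cx = NA_real_,
                         area_um2 = pa, intensity = ii)
        placed <- matrix(NA_real_, np, 2)
        got <- 0L
        for (tr in 1:20000) {
          i <- sample.int(n_somata, 1)
          ang <- runif(1, 0, 2 * pi)
          off <- runif(1, 0, soma_r_px - pr - 8)
          cy <- pts[i, 1] + off * sin(ang); cx <- pts[i, 2] + off * cos(ang)
          if (got > 0L &&
              any(sqrt((placed[seq_len(got), 1] - cy)^2 +
                       (placed[seq_len(got), 2] - cx)^2) < 2 * pr + 8))
            next
          got <- got + 1L
          placed[got, ] <- c(cy, cx)
          asy <- nq_draw_disk(asy, cy, cx, pr, ii, add = FALSE, edge = 0.25)
          pd[got, c("cy", "cx")] <- c(cy, cx)
          if (got == np) break
        }
        if (got < np) stop("could not place puncta without overlap")
        assay_manifest <- list(type = type, puncta = pd)
        peak_intensity <- max(peak_intensity, ii)
      } else if (type %in% c("gh2ax", "fish")) {
        counts <- if (type == "gh2ax")
          rep(assay$foci_per_nucleus %||% 5, length.out = n_somata)
        else rep(assay$foci_counts %||% c(0, 1, 2), length.out = n_somata)
        fa <- assay$focus_area_um2 %||% 0.3
        ii <- assay$intensity %||% 150
        fr <- sqrt(fa / pi) / calib_xy
        rows <- list()
        for (i in seq_len(n_somata)) {
          ki <- counts[i]
          if (ki == 0) next
          # foci placed well inside the nucleus, pairwise separated
          fpts <- matrix(NA_real_, ki, 2)
          got <- 0L
          for (tr in 1:2000) {
            ang <- runif(1, 0, 2 * pi)
            off <- runif(1, 0, (nuclei$b_um[i] - 0.8) / calib_xy - fr)
            cy <- nuclei$cy[i] + off * sin(ang)
            cx <- nuclei$cx[i] + off * cos(ang)
            if (got == 0L ||
                all(sqrt((fpts[seq_len(got), 1] - cy)^2 +
                         (fpts[seq_len(got), 2] - cx)^2) > 2 * fr + 4)) {
              got <- got + 1L; fpts[got, ] <- c(cy, cx)
              if (got == ki) break
            }
          }
          if (got < ki) stop("could not place foci without overlap")
          for (j in seq_len(ki))
            asy <- nq_draw_disk(asy, fpts[j, 1], fpts[j, 2], fr, ii,
                                add = FALSE, edge = 0.25)
          rows[[length(rows) + 1L]] <-
            data.frame(nucleus = i, cy = fpts[, 1], cx = fpts[, 2],
                       area_um2 = fa, intensity = ii)
        }
        foci <- if (length(rows)) do.call(rbind, rows)
          else data.frame(nucleus = integer(), cy = numeric(),
                          cx = numeric(), area_um2 = numeric(),
                          intensity = numeric())
        assay_manifest <- list(type = type, counts = counts, foci = foci)
        peak_intensity <- max(peak_intensity, ii)
      } else stop("unknown assay type: ", type)
    }
    dapi <- dapi + background; map2 <- map2 + background
    if (!is.null(assay)) asy <- asy + background
    psnr <- noise$poisson_snr %||% NULL
    gsd <- noise$gaussian_sd %||% 0
    psf <- noise$psf_sigma_px %||% 0.9
    if (!is.null(psnr) || gsd > 0) {
      dapi <- nq_apply_noise(dapi, psnr, peak_intensity, gsd, psf)
      map2 <- nq_apply_noise(map2, psnr, peak_intensity, gsd, psf)
      if (!is.null(assay))
        asy <- nq_apply_noise(asy, psnr, peak_intensity, gsd, psf)
    }
    list(dapi = image_channel(dapi, calib_xy, role = "dapi"),
         map2 = image_channel(map2, calib_xy, role = "map2"),
         assay = if (!is.null(assay))
           image_channel(asy, calib_xy,
                         role = if (assay$type %in% c("tdp43", "c9orf72",
                                                      "p62", "gh2ax", "fish"))
                           assay$type else "unknown"),
         manifest = list(seed = seed, shape = shape, calib_xy = calib_xy,
                         background = background, somata = somata,
                         nuclei = nuclei, micronuclei = micronuclei,
                         assay = assay_manifest,
                         noise = list(poisson_snr = psnr, gaussian_sd = gsd)))
  })
}

#' Generate a synthetic dendrite stack with planted spines
#'
#' Voxelizes a straight dendritic shaft (cylinder) plus protrusions of
#' prescribed class-prototypical geometry at the reference confocal voxel
#' size (0.066 x 0.066 x 0.390 um by default).  Spines emanate in the
#' well-sampled lateral (y) direction.  Mushroom and thin spines are a neck
#' cylinder capped by a spherical head; stubby spines are a plain wide
#' protrusion without a neck.
#'
#' @param seed RNG seed (used for noise and azimuth signs).
#' @param spines data.frame with columns `class` (mushroom/stubby/thin),
#'   `position_um` (along the shaft), `head_d`, `neck_d` (NA for stubby),
#'   `length` (um, shaft surface to tip).
#' @param shaft_length_um,shaft_radius_um shaft geometry in um.
#' @param voxel_um voxel size `c(x, y, z)` in um.
#' @param intensity foreground intensity.
#' @param gaussian_sd additive noise sd.
#' @return list with `stack` (3D [image_channel()]) and `manifest`.
#' @export
gen_spine_stack <- function(seed, spines,
                            shaft_length_um = 20, shaft_radius_um = 1,
                            voxel_um = c(0.066, 0.066, 0.390),
                            intensity = 200, gaussian_sd = 0) {
  stopifnot(is.data.frame(spines))
  if (any(duplicated(round(spines$position_um, 3))))
    stop("overlapping spines")
  if (nrow(spines) > 1 && min(diff(sort(spines$position_um))) <
      max(spines$head_d, 0.5, na.rm = TRUE) + 0.5)
    stop("overlapping spines")
  nq_with_seed(seed, {
    vx <- voxel_um[1]; vy <- voxel_um[2]; vz <- voxel_um[3]
    max_prot <- if (nrow(spines)) max(spines$length) else 1
    nx <- as.integer(ceiling(shaft_length_um / vx))
    half_y <- shaft_radius_um + max_prot + 0.6
    ny <- as.integer(ceiling(2 * half_y / vy))
    half_z <- shaft_radius_um + 0.6
    nz <- as.integer(ceiling(2 * half_z / vz)) + 2L
    y0 <- (ny / 2) * vy; z0 <- (nz / 2) * vz
    xs <- (seq_len(nx) - 0.5) * vx
    ysv <- (seq_len(ny) - 0.5) * vy
    zsv <- (seq_len(nz) - 0.5) * vz
    dy2 <- outer((ysv - y0)^2, (zsv - z0)^2, "+")     # ny x nz
    shaft_slice <- sqrt(dy2) <= shaft_radius_um
    stack <- array(0, c(nx, ny, nz))
    # same y-z cross-section at every x position along the shaft
    lin <- rep((which(shaft_slice) - 1L) * nx, each = nx) + seq_len(nx)
    stack[lin] <- intensity
    dirs <- sample(c(-1, 1), nrow(spines), replace = TRUE)
    for (s in seq_len(nrow(spines))) {
      cls <- spines$class[s]; x_s <- spines$position_um[s]
      hd <- spines$head_d[s]; nd <- spines$neck_d[s]; L <- spines$length[s]
      dir <- dirs[s]
      xi <- which(abs(xs - x_s) <= max(hd, nd, na.rm = TRUE) / 2 + 2 * vx)
      if (cls == "stubby" || is.na(nd)) {
        # plain cylinder of diameter hd from inside the shaft out to L
        for (i in xi) for (k in seq_len(nz)) {
          perp <- sqrt((xs[i] - x_s)^2 + (zsv[k] - z0)^2)
          if (perp > hd / 2) next
          rad <- dir * (ysv - y0)
          sel <- rad >= shaft_radius_um - 0.2 & rad <= shaft_radius_um + L
          stack[i, sel, k] <- intensity
        }
      } else {
        neck_len <- max(L - hd, 0)
        head_c <- shaft_radius_um + L - hd / 2
        for (i in xi) for (k in seq_len(nz)) {
          perp <- sqrt((xs[i] - x_s)^2 + (zsv[k] - z0)^2)
          rad <- dir * (ysv - y0)
          if (perp <= nd / 2) {
            sel <- rad >= shaft_radius_um - 0.2 &
                   rad <= shaft_radius_um + neck_len
            stack[i, sel, k] <- intensity
          }
          # spherical head
          sel2 <- (xs[i] - x_s)^2 + (rad - head_c)^2 + (zsv[k] - z0)^2 <=
                  (hd / 2)^2
          stack[i, sel2, k] <- intensity
        }
      }
    }
    if (gaussian_sd > 0)
      stack[] <- pmax(stack + stats::rnorm(length(stack), 0, gaussian_sd), 0)
    man <- spines
    man$direction <- dirs
    list(stack = image_channel(stack, calib_xy = vx, calib_z = vz,
                               role = "gfp"),
         manifest = list(seed = seed, spines = man,
                         shaft_length_um = shaft_length_um,
                         shaft_radius_um = shaft_radius_um,
                         voxel_um = voxel_um))
  })
}

#' Generate synthetic calcium traces
#'
#' Builds 1-Hz fluorescence series with a constant baseline and, at each
#' scheduled stimulus onset, an instantaneous-rise, exponential-decay
#' transient of planted peak dF/F0.  Noise-free traces reproduce the
#' planted peak exactly at grid resolution.
#'
#' @param seed RNG seed.
#' @param n_cells number of cells.
#' @param schedule a [stimulus_schedule()] or its data.frame.
#' @param amplitudes matrix (`n_cells` x n events) or named list per
#'   stimulus label of per-cell planted peak dF/F0 values (recycled).
#' @param baseline resting fluorescence F0 (AU).
#' @param tau decay constant in s.
#' @param duration_s total recording length in s (defaults to 60 s past the
#'   last event).
#' @param noise_sd Gaussian noise sd as a fraction of baseline.
#' @return list with `traces` (data.frame: `t` plus one column per cell)
#'   and `manifest` (planted peak matrix, schedule, parameters).
#' @export
gen_calcium_traces <- function(seed, n_cells, schedule, amplitudes,
                               baseline = 100, tau = 10,
                               duration_s = NULL, noise_sd = 0) {
  sched <- if (inherits(schedule, "stimulus_schedule")) schedule$events
           else schedule
  ne <- nrow(sched)
  if (is.list(amplitudes) && !is.data.frame(amplitudes) &&
      !is.matrix(amplitudes)) {
    A <- sapply(sched$label, function(lb)
      rep(amplitudes[[lb]] %||% 0, length.out = n_cells))
    A <- matrix(A, n_cells, ne)
  } else {
    A <- matrix(amplitudes, n_cells, ne)
  }
  colnames(A) <- sched$label
  dur <- duration_s %||% (max(sched$onset) + 60)
  nq_with_seed(seed, {
    t <- 0:(dur - 1)
    traces <- data.frame(t = t)
    for (ci in seq_len(n_cells)) {
      f <- rep(baseline, length(t))
      for (e in seq_len(ne)) {
        on <- sched$onset[e]
        idx <- t >= on
        f[idx] <- f[idx] + baseline * A[ci, e] * exp(-(t[idx] - on) / tau)
      }
      if (noise_sd > 0)
        f <- f + stats::rnorm(length(f), 0, noise_sd * baseline)
      traces[[paste0("cell", ci)]] <- f
    }
    list(traces = traces,
         manifest = list(seed = seed, peaks = A, schedule = sched,
                         baseline = baseline, tau = tau,
                         noise_sd = noise_sd))
  })
}

#' Generate grouped measurements with known effects
#'
#' Draws per-group samples from a stated distribution with stated shifts,
#' for exercising the statistics ladder (type-I error, power, gating).
#'
#' @param seed RNG seed.
#' @param effects named numeric vector: group label -> location shift.
#' @param n per-group sample size (recycled).
#' @param distribution `"normal"` or `"lognormal"`.
#' @param sd sampling sd (normal) or sdlog (lognormal).
#' @return named list of numeric vectors (a `GroupedMeasurements` input)
#'   with attribute `manifest`.
#' @export
gen_group_measurements <- function(seed, effects, n = 20,
                                   distribution = c("normal", "lognormal"),
                                   sd = 1) {
  distribution <- match.arg(distribution)
  n <- rep(n, length.out = length(effects))
  nq_with_seed(seed, {
    out <- lapply(seq_along(effects), function(i) {
      if (distribution == "normal")
        stats::rnorm(n[i], mean = effects[i], sd = sd)
      else
        stats::rlnorm(n[i], meanlog = effects[i], sdlog = sd)
    })
    names(out) <- names(effects)
    attr(out, "manifest") <- list(seed = seed, effects = effects, n = n,
                                  distribution = distribution, sd = sd)
    out
  })
}
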