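## Nuclear-channel preprocessing: unsharp mask -> CLAHE -> median filter.

## Fiji-style unsharp mask: subtract a weighted Gaussian blur and rescale.
nq_unsharp <- function(x, radius, amount) {
  if (radius <= 0) stop("unsharp radius must be positive")
  if (amount < 0 || amount >= 1) stop("unsharp amount must be in [0, 1)")
  g <- EBImage::gblur(x, sigma = radius)
  (x - amount * g) / (1 - amount)
}

## Contrast-limited adaptive histogram equalization (tile-interpolated).
## Histograms use `nbins` bins over the image's native range; each tile's
## histogram is clipped at max_slope times the uniform level and the excess
## redistributed, then pixel values are mapped through the bilinear
## interpolation of the four surrounding tile CDFs.
nq_clahe <- function(x, blocksize = 127, nbins = 256, max_slope = 3) {
  if (blocksize <= 1) stop("clahe blocksize must be > 1")
  mn <- min(x); mx <- max(x)
  if (mx <= mn) return(x)                      # flat field is left flat
  nr <- nrow(x); nc <- ncol(x)
  nty <- max(1L, as.integer(ceiling(nr / blocksize)))
  ntx <- max(1L, as.integer(ceiling(nc / blocksize)))
  ys <- floor(seq(0, nr, length.out = nty + 1))
  xs <- floor(seq(0, nc, length.out = ntx + 1))
  bin <- pmin(nbins - 1L, as.integer(floor((x - mn) / (mx - mn) * nbins)))
  dim(bin) <- dim(x)
  M <- matrix(0, nbins, nty * ntx)             # per-tile CDF mappings
  cy <- numeric(nty); cx <- numeric(ntx)
  for (tx in seq_len(ntx)) {
    for (ty in seq_len(nty)) {
      rows <- (ys[ty] + 1):ys[ty + 1]
      cols <- (xs[tx] + 1):xs[tx + 1]
      h <- tabulate(bin[rows, cols] + 1L, nbins)
      npx <- length(rows) * length(cols)
      clip <- max_slope * npx / nbins
      excess <- sum(pmax(h - clip, 0))
      h <- pmin(h, clip) + excess / nbins
      M[, (tx - 1L) * nty + ty] <- cumsum(h) / npx
    }
  }
  cy <- (ys[-length(ys)] + ys[-1] + 1) / 2     # tile centers, 1-based px
  cx <- (xs[-length(xs)] + xs[-1] + 1) / 2
  # bilinear interpolation weights between surrounding tile centers
  ri <- seq_len(nr); ci <- seq_len(nc)
  ty_lo <- pmin(pmax(findInterval(ri, cy), 1L), max(nty - 1L, 1L))
  tx_lo <- pmin(pmax(findInterval(ci, cx), 1L), max(ntx - 1L, 1L))
  ty_hi <- pmin(ty_lo + 1L, nty)
  tx_hi <- pmin(tx_lo + 1L, ntx)
  wy <- if (nty > 1)
    pmin(pmax((ri - cy[ty_lo]) / pmax(cy[ty_hi] - cy[ty_lo], 1e-9), 0), 1)
  else rep(0, nr)
  wx <- if (ntx > 1)
    pmin(pmax((ci - cx[tx_lo]) / pmax(cx[tx_hi] - cx[tx_lo], 1e-9), 0), 1)
  else rep(0, nc)
  b1 <- bin + 1L
  WY <- matrix(wy, nr, nc); WX <- matrix(wx, nr, nc, byrow = TRUE)
  tile_k <- function(tyv, txv)
    matrix((txv[col(bin)] - 1L) * nty + tyv[row(bin)], nr, nc)
  v <- (1 - WY) * (1 - WX) * M[cbind(as.vector(b1), as.vector(tile_k(ty_lo, tx_lo)))] +
       (1 - WY) * WX       * M[cbind(as.vector(b1), as.vector(tile_k(ty_lo, tx_hi)))] +
       WY * (1 - WX)       * M[cbind(as.vector(b1), as.vector(tile_k(ty_hi, tx_lo)))] +
       WY * WX             * M[cbind(as.vector(b1), as.vector(tile_k(ty_hi, tx_hi)))]
  out <- mn + v * (mx - mn)
  dim(out) <- dim(x)
  out
}

## Median filter on a (2r+1)^2 window via EBImage (input normalized to [0,1]).
nq_median <- function(x, radius) {
  if (radius <= 0) stop("median radius must be positive")
  mx <- max(x)
  if (mx <= 0) return(x)
  EBImage::medianFilter(x / mx, size = as.integer(radius)) * mx
}

#' Preprocess a DAPI channel for nuclear masking
#'
#' The fixed enhancement chain applied before binarizing nuclei: unsharp
#' mask (Gaussian radius, mask weight), contrast-limited adaptive histogram
#' equalization (CLAHE) and a median filter, in that order; the output is
#' clipped to be non-negative.  The defaults are the standard recipe:
#' unsharp radius 1 px / weight 0.60, CLAHE blocksize 127 px / 256 bins /
#' maximum slope 3, median radius 3 px.
#'
#' @param dapi a 2D [image_channel()].
#' @param unsharp_radius Gaussian radius (px) of the unsharp mask.
#' @param unsharp_amount unsharp mask weight in [0, 1).
#' @param clahe_blocksize CLAHE tile size in px.
#' @param clahe_bins CLAHE histogram bins.
#' @param clahe_max_slope CLAHE clip limit (multiple of the uniform level).
#' @param median_radius median filter radius in px.
#' @return an [image_channel()] with the same calibration and role.
#' @export
preprocess_nuclear <- function(dapi, unsharp_radius = 1, unsharp_amount = 0.60,
                               clahe_blocksize = 127, clahe_bins = 256,
                               clahe_max_slope = 3, median_radius = 3) {
  stopifnot(inherits(dapi, "image_channel"))
  if (length(dim(dapi$pixels)) != 2L) stop("dapi must be 2D")
  x <- nq_unsharp(dapi$pixels, unsharp_radius, unsharp_amount)
  x <- nq_clahe(x, blocksize = clahe_blocksize, nbins = clahe_bins,
                max_slope = clahe_max_slope)
  x <- pmax(x, 0)        # the median filter operates on intensities, not residuals
  x <- nq_median(x, median_radius)
  x <- pmax(x, 0)
  dim(x) <- dim(dapi$pixels)
  image_channel(x, dapi$calib_xy, dapi$calib_z, dapi$role)
}
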