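## Automatic histogram thresholding.
##
## All methods operate on the image's native dynamic range quantized to 256
## equal-width bins (the Fiji convention, "histogram = 256").  A method
## returns the index t of the last background bin; foreground is every pixel
## falling in a bin strictly above t, i.e. strictly above every
## background-classified intensity.

nq_hist256 <- function(x) {
  mn <- min(x); mx <- max(x)
  if (mx <= mn) stop("degenerate histogram")
  w <- (mx - mn) / 256
  b <- pmin(255L, as.integer(floor((x - mn) / w)))
  list(counts = tabulate(b + 1L, 256L), bins = b, mn = mn, mx = mx, w = w)
}

## Otsu: maximize between-class variance over all candidate splits.
nq_thr_otsu <- function(h) {
  p <- h$counts / sum(h$counts)
  i <- 0:255
  P0 <- cumsum(p)
  m <- cumsum(p * i)
  mt <- m[256]
  t <- 1:255                                  # split after bin t-1
  w0 <- P0[t]; w1 <- 1 - w0
  valid <- w0 > 0 & w1 > 0
  bcv <- rep(-Inf, 255)
  bcv[valid] <- ((mt * w0[valid] - m[t][valid])^2 /
                   (w0[valid] * w1[valid]))
  which.max(bcv) - 1L                          # last background bin (0-based)
}

## Kapur max-entropy: maximize the sum of Shannon entropies of the two
## classes' normalized histograms.
nq_thr_maxentropy <- function(h) {
  nq_thr_entropy(h, alpha = 1)
}

## Renyi entropy of order alpha (alpha = 1 is the Shannon/Kapur limit).
nq_thr_renyi <- function(h, alpha = 2) {
  nq_thr_entropy(h, alpha = alpha)
}

nq_thr_entropy <- function(h, alpha) {
  p <- h$counts / sum(h$counts)
  best <- -Inf; best_t <- 127L
  P0 <- cumsum(p)
  for (t in 1:255) {
    w0 <- P0[t]; w1 <- 1 - w0
    if (w0 <= 0 || w1 <= 0) next
    p0 <- p[1:t] / w0
    p1 <- p[(t + 1):256] / w1
    p0 <- p0[p0 > 0]; p1 <- p1[p1 > 0]
    if (alpha == 1) {
      val <- -sum(p0 * log(p0)) - sum(p1 * log(p1))
    } else {
      val <- (log(sum(p0^alpha)) + log(sum(p1^alpha))) / (1 - alpha)
    }
    if (val > best) { best <- val; best_t <- t }
  }
  best_t - 1L
}

## Li: iterative minimum cross-entropy on the quantized histogram
## (bin-center intensities, shifted to be strictly positive).
nq_thr_li <- function(h) {
  cc <- (0:255 + 0.5) * h$w + h$w              # shifted bin centers, > 0
  n <- h$counts
  t_cur <- sum(n * cc) / sum(n)                # start at the mean
  for (iter in 1:100) {
    below <- cc <= t_cur
    if (!any(n[below] > 0) || !any(n[!below] > 0)) break
    mb <- sum(n[below] * cc[below]) / sum(n[below])
    mf <- sum(n[!below] * cc[!below]) / sum(n[!below])
    t_new <- (mb - mf) / (log(mb) - log(mf))
    if (!is.finite(t_new) || abs(t_new - t_cur) < h$w / 1000) {
      t_cur <- if (is.finite(t_new)) t_new else t_cur
      break
    }
    t_cur <- t_new
  }
  t_bin <- as.integer(floor((t_cur - h$w) / h$w))
  max(0L, min(254L, t_bin))
}

## Threshold computed from the histogram of the pixels inside `within`
## only (e.g. "the remaining signal" after masking); returns the logical
## foreground raster restricted to `within`, plus the threshold record.
nq_threshold_within <- function(pixels, within, method) {
  h <- nq_hist256(pixels[within])
  t_bin <- switch(method,
                  li = nq_thr_li(h),
                  otsu = nq_thr_otsu(h),
                  renyi_entropy = nq_thr_renyi(h),
                  max_entropy = nq_thr_maxentropy(h))
  thr_value <- h$mn + (t_bin + 1) * h$w
  fg <- within & pixels >= thr_value
  list(pixels = fg,
       threshold = list(method = method, bin = t_bin, value = thr_value))
}

#' Automatic image thresholding
#'
#' Computes a global threshold on the 256-bin histogram of the image's
#' native dynamic range and returns the binary foreground mask (pixels
#' strictly above the threshold).  Methods: `"li"` (minimum cross-entropy),
#' `"otsu"` (between-class variance), `"renyi_entropy"` (Renyi entropy sum,
#' order 2) and `"max_entropy"` (Kapur entropy sum).
#'
#' @param img a 2D [image_channel()] with at least two distinct intensities.
#' @param method thresholding criterion.
#' @return a [binary_mask()]; the chosen threshold (bin index and intensity
#'   value) is recorded in `provenance$threshold`.
#' @examples
#' img <- image_channel(matrix(c(10, 200)[1 + (1:100 > 50)], 10),
#'                      calib_xy = 0.1)
#' sum(auto_threshold(img, "otsu")$pixels)
#' @export
auto_threshold <- function(img,
                           method = c("li", "otsu", "renyi_entropy",
                                      "max_entropy")) {
  stopifnot(inherits(img, "image_channel"))
  method <- match.arg(method)
  if (length(dim(img$pixels)) != 2L) stop("img must be 2D")
  h <- nq_hist256(img$pixels)
  t_bin <- switch(method,
                  li = nq_thr_li(h),
                  otsu = nq_thr_otsu(h),
                  renyi_entropy = nq_thr_renyi(h),
                  max_entropy = nq_thr_maxentropy(h))
  px <- h$bins > t_bin
  dim(px) <- dim(img$pixels)
  thr_value <- h$mn + (t_bin + 1) * h$w
  binary_mask(px, img$calib_xy, img$calib_z,
              provenance = list(threshold = list(method = method,
                                                 bin = t_bin,
                                                 value = thr_value)))
}
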