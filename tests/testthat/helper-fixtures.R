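# Shared fixture builders (all generated in code; no files).

# logical disk mask of equivalent radius r_um at calib um/px
disk_mask <- function(r_um, calib = 0.1, pad_px = 6, extra = NULL) {
  r_px <- r_um / calib
  n <- ceiling(2 * r_px) + 2 * pad_px
  m <- matrix(FALSE, n, n)
  ctr <- (n + 1) / 2
  for (i in 1:n) for (j in 1:n)
    if ((i - ctr)^2 + (j - ctr)^2 <= r_px^2) m[i, j] <- TRUE
  m
}

# place several disks into one mask without touching
multi_disk_mask <- function(r_ums, calib = 0.1, gap_px = 12) {
  sizes <- sapply(r_ums, function(r) ceiling(2 * r / calib) + 8)
  n <- max(sizes) + 8
  total_w <- sum(sizes) + gap_px * (length(r_ums) + 1)
  m <- matrix(FALSE, n, total_w)
  x0 <- gap_px
  centers <- list()
  for (k in seq_along(r_ums)) {
    r_px <- r_ums[k] / calib
    cy <- n / 2; cx <- x0 + sizes[k] / 2
    for (i in 1:n) for (j in max(1, floor(cx - r_px - 2)):min(total_w, ceiling(cx + r_px + 2)))
      if ((i - cy)^2 + (j - cx)^2 <= r_px^2) m[i, j] <- TRUE
    centers[[k]] <- c(cy, cx)
    x0 <- x0 + sizes[k] + gap_px
  }
  attr(m, "centers") <- centers
  m
}

# filled rotated ellipse raster (semi-axes in px)
ellipse_raster <- function(a_px, b_px, theta = 0, pad = 6) {
  n <- ceiling(2 * a_px) + 2 * pad
  m <- matrix(0L, n, n)
  ctr <- (n + 1) / 2
  for (i in 1:n) for (j in 1:n) {
    di <- i - ctr; dj <- j - ctr
    u <- ((di * cos(theta) + dj * sin(theta)) / a_px)^2 +
      ((-di * sin(theta) + dj * cos(theta)) / b_px)^2
    if (u <= 1) m[i, j] <- 1L
  }
  m
}

# independent exhaustive-search Otsu oracle on the same 256-bin histogram
otsu_bruteforce <- function(x) {
  mn <- min(x); mx <- max(x)
  w <- (mx - mn) / 256
  b <- pmin(255L, floor((x - mn) / w))
  best <- -Inf; best_t <- NA
  for (t in 0:254) {
    lo <- x[b <= t]; hi <- x[b > t]
    if (!length(lo) || !length(hi)) next
    v <- length(lo) * length(hi) * (mean(lo) - mean(hi))^2
    if (v > best) { best <- v; best_t <- t }
  }
  best_t
}

# independent rule-table spine classifier (kept deliberately separate from
# the package implementation)
spine_rule_table <- function(head, len, neck, p) {
  has_neck <- !is.na(neck) && (head / neck) >= p$neck_ratio
  if (has_neck && head >= p$mushroom_size_um) return("mushroom")
  if ((len / head) >= p$thin_ratio) return("thin")
  "stubby"
}

# brute-force optimal 2-partition within-SS (all 2^n-2 assignments)
best_two_partition_ss <- function(x) {
  n <- length(x)
  best <- Inf
  for (code in 1:(2^n - 2)) {
    g <- as.logical(bitwAnd(code, 2^(0:(n - 1))))
    a <- x[g]; b <- x[!g]
    ss <- sum((a - mean(a))^2) + sum((b - mean(b))^2)
    if (ss < best) best <- ss
  }
  best
}
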