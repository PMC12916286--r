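test_that("all threshold methods separate a two-level image exactly", {
  px <- matrix(10, 40, 40)
  px[, 21:40] <- 200
  img <- image_channel(px, calib_xy = 0.1)
  for (m in c("li", "otsu", "renyi_entropy", "max_entropy")) {
    mask <- auto_threshold(img, m)
    expect_identical(unname(mask$pixels), unname(px == 200), info = m)
    expect_true(is.numeric(mask$provenance$threshold$value))
  }
})

test_that("Otsu threshold matches the exhaustive between-class-variance oracle", {
  set.seed(11)
  for (rep in 1:3) {
    x <- c(rnorm(5000, 50, 10), rnorm(5000, 180, 10))
    x <- pmax(x, 0)
    img <- image_channel(matrix(x, 100), calib_xy = 0.1)
    mask <- auto_threshold(img, "otsu")
    expect_equal(mask$provenance$threshold$bin, otsu_bruteforce(x))
  }
})

test_that("degenerate (constant) images are rejected", {
  img <- image_channel(matrix(7, 10, 10), calib_xy = 0.1)
  expect_error(auto_threshold(img, "otsu"), "degenerate histogram")
  expect_error(auto_threshold(img, "li"), "degenerate histogram")
  expect_error(auto_threshold(image_channel(matrix(1:4, 2), 0.1), "nope"))
})

test_that("remove_small_by_radius follows the sqrt(area/pi) oracle with strict <", {
  calib <- 0.1
  m <- multi_disk_mask(c(3, 8), calib = calib)
  mask <- binary_mask(m, calib)
  out <- remove_small_by_radius(mask, 5)
  lab <- label_mask(out)
  expect_equal(n_labels(lab), 1L)
  # survivor is the big disk: oracle check on its equivalent radius
  area <- sum(out$pixels) * calib^2
  expect_gt(sqrt(area / pi), 5)
  # boundary: equivalent radius a hair above the gate is retained under the
  # strict-< rule, a hair below is removed
  blob <- function(n_px) {
    sq <- matrix(FALSE, 200, 200)
    sq[seq_len(n_px)] <- TRUE
    binary_mask(sq, 1)
  }
  n_at <- ceiling(pi * 25)                  # 79 px: r = 5.0146 um
  expect_equal(sum(remove_small_by_radius(blob(n_at), 5)$pixels), n_at)
  expect_equal(sum(remove_small_by_radius(blob(n_at - 2), 5)$pixels), 0)
  # inclusive mode removes the just-above blob's <= twin semantics
  expect_equal(sum(remove_small_by_radius(blob(n_at - 2), 5,
                                          inclusive = TRUE)$pixels), 0)
  # empty in, empty out; and errors
  empty <- binary_mask(matrix(FALSE, 10, 10), calib)
  expect_equal(sum(remove_small_by_radius(empty, 5)$pixels), 0)
  expect_error(remove_small_by_radius(mask, -1), "positive")
})

test_that("remove_small_by_area drops sub-threshold blobs only", {
  calib <- 0.1
  # 1 um^2 = 100 px, 10 um^2 = 1000 px at 0.1 um/px
  m <- matrix(FALSE, 60, 120)
  m[10:19, 10:19] <- TRUE           # 100 px = 1 um^2
  m[20:44, 60:99] <- TRUE           # 1000 px = 10 um^2
  mask <- binary_mask(m, calib)
  out <- remove_small_by_area(mask, 2)
  expect_equal(sum(out$pixels), 1000)
  # all blobs above threshold -> identity
  out2 <- remove_small_by_area(mask, 0.5)
  expect_identical(out2$pixels, mask$pixels)
})

test_that("fill_holes_max_area fills only enclosed holes up to the ceiling", {
  calib <- 1
  ring <- function(hole_w) {
    m <- matrix(FALSE, 20, 20)
    m[5:15, 5:15] <- TRUE
    m[8:(7 + hole_w), 8:(7 + hole_w)] <- FALSE
    m
  }
  small <- binary_mask(ring(1), calib)      # 1 px = 1 um^2 hole... use 3 um^2
  m3 <- matrix(FALSE, 20, 20); m3[5:15, 5:15] <- TRUE; m3[8, 8:10] <- FALSE
  small <- binary_mask(m3, calib)           # 3 um^2 hole
  filled <- fill_holes_max_area(small, 4)
  expect_equal(sum(filled$pixels), sum(m3) + 3)
  m6 <- matrix(FALSE, 20, 20); m6[5:15, 5:15] <- TRUE; m6[8:9, 8:10] <- FALSE
  big <- binary_mask(m6, calib)             # 6 um^2 hole stays
  expect_identical(fill_holes_max_area(big, 4)$pixels, m6)
  # border-touching background is never filled
  mb <- matrix(TRUE, 10, 10); mb[1:3, 5] <- FALSE
  expect_identical(fill_holes_max_area(binary_mask(mb, calib), 100)$pixels, mb)
  # no holes -> identity
  solid <- binary_mask(matrix(TRUE, 5, 5), calib)
  expect_identical(fill_holes_max_area(solid, 4)$pixels, solid$pixels)
})

test_that("removal and filling are idempotent and monotone", {
  set.seed(4)
  px <- matrix(runif(10000) > 0.6, 100, 100)
  mask <- binary_mask(px, 0.2)
  r1 <- remove_small_by_radius(mask, 1)
  r2 <- remove_small_by_radius(r1, 1)
  expect_identical(r1$pixels, r2$pixels)
  expect_true(all(px[r1$pixels]))                    # never gains foreground
  f1 <- fill_holes_max_area(mask, 2)
  f2 <- fill_holes_max_area(f1, 2)
  expect_identical(f1$pixels, f2$pixels)
  expect_true(all(f1$pixels[mask$pixels]))           # never loses foreground
})

test_that("watershed splits touching disks and respects trivial cases", {
  calib <- 0.1
  # two overlapping disks: centers 8 um apart, radii 5 um
  n <- 240
  m <- matrix(FALSE, n, n)
  for (i in 1:n) for (j in 1:n) {
    if ((i - 120)^2 + (j - 80)^2 <= 50^2 ||
        (i - 120)^2 + (j - 160)^2 <= 50^2) m[i, j] <- TRUE
  }
  lab <- watershed_split(binary_mask(m, calib))
  expect_equal(n_labels(lab), 2L)
  single <- watershed_split(binary_mask(disk_mask(5), calib))
  expect_equal(n_labels(single), 1L)
  empty <- watershed_split(binary_mask(matrix(FALSE, 10, 10), calib))
  expect_equal(n_labels(empty), 0L)
})

test_that("measure_regions reports exact areas, sums and ellipse eccentricity", {
  # 10x10 px square at 0.5 um/px -> 25 um^2
  lab <- matrix(0L, 20, 20); lab[5:14, 5:14] <- 1L
  lr <- labeled_regions(lab, calib_xy = 0.5)
  m <- measure_regions(lr)
  expect_equal(m$area_um2, 25)
  expect_equal(m$eccentricity, 0, tolerance = 1e-9)
  # uniform intensity 3 over a 100-px object -> sum 300
  img <- image_channel(matrix(3, 20, 20), calib_xy = 0.5)
  expect_equal(measure_regions(lr, img)$sum_intensity, 300)
  # rasterized ellipse a=10 um, b=5 um -> eccentricity within 2%
  e <- ellipse_raster(100, 50, theta = 0.4)
  lr2 <- labeled_regions(e, calib_xy = 0.1)
  m2 <- measure_regions(lr2)
  expect_equal(m2$eccentricity, sqrt(100 - 25) / 10, tolerance = 0.02)
  expect_equal(m2$major_axis_a / m2$minor_axis_b, 2, tolerance = 0.03)
  # total area identity: foreground px count times calib^2, exactly
  expect_equal(sum(m2$area_um2), sum(e > 0) * 0.01)
  # empty labels -> empty frame
  expect_equal(nrow(measure_regions(labeled_regions(matrix(0L, 5, 5), 1))), 0)
  # RegionRecord invariant: ecc formula consistent with reported axes
  expect_equal(m2$eccentricity,
               sqrt(m2$major_axis_a^2 - m2$minor_axis_b^2) / m2$major_axis_a,
               tolerance = 1e-9)
})

test_that("preprocess_nuclear is identity on flat fields and removes impulses", {
  flat <- image_channel(matrix(50, 64, 64), calib_xy = 0.1)
  out <- preprocess_nuclear(flat)
  expect_equal(out$pixels, flat$pixels, tolerance = 1e-6)
  imp <- matrix(10, 64, 64); imp[32, 32] <- 1000
  outi <- preprocess_nuclear(image_channel(imp, calib_xy = 0.1))
  # median radius 3 wipes a single-pixel impulse
  expect_lt(max(outi$pixels[20:44, 20:44]) / max(outi$pixels), 1.5)
  expect_error(preprocess_nuclear(flat, unsharp_radius = -1), "positive")
  # published defaults are baked into the signature
  f <- formals(preprocess_nuclear)
  expect_equal(c(f$unsharp_radius, f$unsharp_amount, f$clahe_blocksize,
                 f$clahe_bins, f$clahe_max_slope, f$median_radius),
               c(1, 0.60, 127, 256, 3, 3))
})

test_that("image containers validate their invariants", {
  expect_error(image_channel(matrix(-1, 2, 2), 0.1), ">= 0")
  expect_error(image_channel(matrix(1, 2, 2), -0.1), "positive")
  expect_error(image_channel(array(1, c(2, 2, 2)), 0.1), "calib_z")
  expect_error(labeled_regions(matrix(c(0L, 2L), 2, 2), 0.1), "contiguous")
  expect_silent(binary_mask(matrix(c(0, 1), 2, 2), 0.1))
})
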