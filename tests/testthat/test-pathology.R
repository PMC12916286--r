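test_that("MAP2 masks recover planted somata and reject pure noise", {
  fx <- gen_if_image(seed = 101, n_somata = 1, assay = NULL)
  man <- fx$manifest$somata
  for (recipe in c("c9orf72", "tdp43", "p62")) {
    m <- make_map2_mask(fx$map2, recipe)
    # planted-soma overlap: >= 90% of the true disk is inside the mask
    r_px <- man$radius_um / fx$manifest$calib_xy
    truth <- matrix(FALSE, nrow(m$pixels), ncol(m$pixels))
    for (i in seq_len(nrow(truth))) {
      dj2 <- r_px^2 - (i - man$cy)^2
      if (dj2 > 0) {
        j <- max(1, ceiling(man$cx - sqrt(dj2))):min(ncol(truth), floor(man$cx + sqrt(dj2)))
        truth[i, j] <- TRUE
      }
    }
    expect_gt(sum(m$pixels & truth) / sum(truth), 0.9, label = recipe)
  }
  # sparse specks far below any soma size: all removed by the size gates
  set.seed(5)
  spk <- matrix(5, 512, 512)
  spk[sample.int(512^2, 200)] <- 150
  noise <- image_channel(spk, calib_xy = 0.1, role = "map2")
  expect_equal(sum(make_map2_mask(noise, "tdp43")$pixels), 0)
})

test_that("tdp43 MAP2 recipe splits bridge-connected somata via watershed", {
  calib <- 0.1
  px <- matrix(5, 400, 400)
  for (i in 1:400) for (j in 1:400) {
    if ((i - 200)^2 + (j - 120)^2 <= 70^2 ||
        (i - 200)^2 + (j - 280)^2 <= 70^2) px[i, j] <- 150
  }
  px[200, 190:210] <- 150                      # 1-px bridge
  m <- make_map2_mask(image_channel(px, calib, role = "map2"), "tdp43")
  expect_gte(max(m$provenance$labels), 2L)
})

test_that("nuclear masks recover planted nuclei; gh2ax excludes sub-1.5um2 debris", {
  fx <- gen_if_image(seed = 102, shape = c(640L, 640L), n_somata = 6,
                     soma_radius_um = 9)
  man <- fx$manifest$nuclei
  for (recipe in c("c9orf72", "tdp43", "gh2ax")) {
    nl <- make_nuclear_mask(fx$dapi, recipe)
    expect_equal(n_labels(nl), 6L, label = recipe)
    meas <- measure_regions(nl)
    # match each planted nucleus to the label under its centre
    lab_at <- nl$labels[cbind(round(man$cy), round(man$cx))]
    expect_true(all(lab_at > 0), label = recipe)
    expect_equal(meas$area_um2[lab_at], man$area_um2, tolerance = 0.1,
                 label = recipe)
  }
  # planted debris speck of ~0.8 um^2 is excluded from gh2ax total area
  px <- fx$dapi$pixels
  px <- nq <- px
  spk2 <- neuroquant:::nq_draw_disk(px, 20, 20, sqrt(0.8 / pi) / 0.1, 180,
                                    add = FALSE)
  nl2 <- make_nuclear_mask(image_channel(spk2, 0.1, role = "dapi"), "gh2ax")
  nl1 <- make_nuclear_mask(fx$dapi, "gh2ax")
  expect_equal(nl2$provenance$total_nuclear_area_um2,
               nl1$provenance$total_nuclear_area_um2, tolerance = 0.01)
  # empty DAPI -> degenerate histogram; uniform-noise DAPI -> no nuclei
  expect_error(make_nuclear_mask(image_channel(matrix(0, 64, 64), 0.1),
                                 "c9orf72"), "degenerate")
})

test_that("C9orf72 intensity is the union-sum over MAP2 area and is linear", {
  fx <- gen_if_image(seed = 103, assay = list(type = "c9orf72",
                                              intensity = 120))
  r <- c9orf72_intensity(fx$map2, fx$dapi, fx$assay)
  # planted uniform density: metric times calib^2 recovers intensity + bg
  dens <- r$metrics$c9_sum_per_map2_area * fx$manifest$calib_xy^2 *
    r$qc$map2_area_um2 / r$qc$union_area_um2
  expect_equal(dens, 120 + fx$manifest$background, tolerance = 0.05 * 125)
  # homogeneity: doubling the channel doubles the metric
  double <- image_channel(fx$assay$pixels * 2, fx$assay$calib_xy,
                          role = "c9orf72")
  r2 <- c9orf72_intensity(fx$map2, fx$dapi, double)
  expect_equal(r2$metrics$c9_sum_per_map2_area,
               2 * r$metrics$c9_sum_per_map2_area, tolerance = 1e-9)
  # empty MAP2 mask errors
  blank <- image_channel(matrix(0, 512, 512), 0.1, role = "map2")
  expect_error(c9orf72_intensity(blank, fx$dapi, fx$assay))
})

test_that("TDP-43 ratio recovers planted values and obeys its edge cases", {
  for (planted in c(0.5, 2.0)) {
    fx <- gen_if_image(seed = 110 + planted * 10,
                       assay = list(type = "tdp43", cyto_ratio = planted))
    r <- tdp43_cyto_nuclear_ratio(fx$map2, fx$dapi, fx$assay)
    expect_equal(r$metrics$cyto_nuclear_ratio, planted,
                 tolerance = 0.1 * planted)
  }
  # uniform signal over the whole cell -> ratio 1 within 5%
  fx <- gen_if_image(seed = 115, assay = list(type = "tdp43", cyto_ratio = 1))
  r1 <- tdp43_cyto_nuclear_ratio(fx$map2, fx$dapi, fx$assay)
  expect_equal(r1$metrics$cyto_nuclear_ratio, 1.0, tolerance = 0.05)
  # invariance under global scaling of the TDP-43 channel
  scaled <- image_channel(fx$assay$pixels * 3.7, 0.1, role = "tdp43")
  rs <- tdp43_cyto_nuclear_ratio(fx$map2, fx$dapi, scaled)
  expect_equal(rs$metrics$cyto_nuclear_ratio, r1$metrics$cyto_nuclear_ratio,
               tolerance = 1e-9)
  # zero cytosolic signal -> ratio ~0
  fx0 <- gen_if_image(seed = 116, background = 0,
                      assay = list(type = "tdp43", cyto_ratio = 0))
  r0 <- tdp43_cyto_nuclear_ratio(fx0$map2, fx0$dapi, fx0$assay)
  expect_lt(r0$metrics$cyto_nuclear_ratio, 0.02)
})

test_that("p62 metrics recover planted puncta and enforce the admission window", {
  fx <- gen_if_image(seed = 120,
                     assay = list(type = "p62", n_puncta = 15,
                                  punctum_area_um2 = 0.25))
  r <- p62_vesicle_metrics(fx$map2, fx$assay)
  expect_equal(r$qc$n_vesicles, 15L)
  expect_equal(r$metrics$count_per_map2_area, 15 / r$qc$map2_area_um2,
               tolerance = 1e-9)
  expect_equal(r$metrics$mean_vesicle_area, 0.25, tolerance = 0.1)
  # a 2 um^2 blob is outside [0.01, 1] um^2: metrics unchanged vs without it
  big <- neuroquant:::nq_draw_disk(fx$assay$pixels,
                                   fx$manifest$somata$cy[1],
                                   fx$manifest$somata$cx[1],
                                   sqrt(2 / pi) / 0.1, 120, add = FALSE,
                                   edge = 0.25)
  rb <- p62_vesicle_metrics(fx$map2, image_channel(big, 0.1, role = "p62"))
  expect_equal(rb$qc$n_vesicles, r$qc$n_vesicles)
  # no puncta at all -> zero counts and sizes
  none <- image_channel(matrix(5, 512, 512), 0.1, role = "p62")
  rn <- p62_vesicle_metrics(fx$map2, none)
  expect_equal(rn$metrics$count_per_map2_area, 0)
  expect_equal(rn$metrics$mean_vesicle_area, 0)
})

test_that("gh2ax metrics count planted foci and scale correctly", {
  fx <- gen_if_image(seed = 130, n_somata = 4, soma_radius_um = 10,
                     assay = list(type = "gh2ax", foci_per_nucleus = 5))
  r <- gh2ax_metrics(fx$dapi, fx$assay)
  expect_equal(r$qc$n_foci, 20L)
  expect_equal(r$metrics$foci_count_per_nuclear_area,
               20 / sum(fx$manifest$nuclei$area_um2), tolerance = 0.1)
  # doubling the gain doubles sum intensity, leaves the count unchanged
  dbl <- image_channel(fx$assay$pixels * 2, 0.1, role = "gh2ax")
  r2 <- gh2ax_metrics(fx$dapi, dbl)
  expect_equal(r2$metrics$sum_intensity_per_nuclear_area,
               2 * r$metrics$sum_intensity_per_nuclear_area, tolerance = 1e-9)
  expect_equal(r2$qc$n_foci, r$qc$n_foci)
  # zero channel -> all metrics 0
  r0 <- gh2ax_metrics(fx$dapi, image_channel(matrix(0, 512, 512), 0.1,
                                             role = "gh2ax"))
  expect_equal(r0$metrics$sum_intensity_per_nuclear_area, 0)
  expect_equal(r0$metrics$foci_count_per_nuclear_area, 0)
  expect_equal(r0$metrics$mean_focus_area, 0)
})

test_that("RNA foci per nucleus are recovered exactly on noise-free fixtures", {
  planted <- c(0, 1, 2, 3, 6)
  fx <- gen_if_image(seed = 140, shape = c(640L, 640L), n_somata = 5,
                     soma_radius_um = 9,
                     assay = list(type = "fish", foci_counts = planted))
  ft <- rna_foci_per_nucleus(fx$dapi, fx$assay)
  expect_equal(sort(ft$foci_count), sort(planted))
  # no FISH signal -> all zero counts
  ft0 <- rna_foci_per_nucleus(fx$dapi,
                              image_channel(matrix(0, 640, 640), 0.1,
                                            role = "fish"))
  expect_equal(ft0$foci_count, rep(0L, 5))
})

test_that("a focus straddling two nuclei is counted once, by centroid", {
  calib <- 0.1
  dapi <- matrix(0, 300, 300)
  # two abutting nuclei (disks) with a focus centred in the left one but
  # overlapping the boundary
  for (i in 1:300) for (j in 1:300) {
    if ((i - 150)^2 + (j - 95)^2 <= 58^2 ||
        (i - 150)^2 + (j - 212)^2 <= 58^2) dapi[i, j] <- 180
  }
  fish <- matrix(0, 300, 300)
  fish <- neuroquant:::nq_draw_disk(fish, 150, 148, 4, 150, add = FALSE,
                                    edge = 0.25)
  ft <- rna_foci_per_nucleus(image_channel(dapi, calib, role = "dapi"),
                             image_channel(fish, calib, role = "fish"))
  expect_equal(sum(ft$foci_count), 1L)
})

test_that("foci_summary computes fraction, positive mean and range", {
  s <- foci_summary(data.frame(foci_count = c(1, 2, 3, 0, 0, 0)))
  expect_equal(s$fraction_positive, 50)
  expect_equal(s$mean_foci_positive, 2)
  expect_equal(s$range, c(1, 3))
  s0 <- foci_summary(data.frame(foci_count = rep(0L, 4)))
  expect_equal(s0$fraction_positive, 0)
  expect_true(is.na(s0$mean_foci_positive))
  expect_error(foci_summary(data.frame(foci_count = integer())), "empty")
  # complement identity: positive + zero fractions = 100%
  set.seed(9)
  cnt <- rpois(40, 0.7)
  s1 <- foci_summary(data.frame(foci_count = cnt))
  expect_equal(s1$fraction_positive + 100 * mean(cnt == 0) * 1, 100)
})

test_that("recipes are deterministic", {
  fx <- gen_if_image(seed = 150, assay = list(type = "tdp43",
                                              cyto_ratio = 0.5))
  r1 <- tdp43_cyto_nuclear_ratio(fx$map2, fx$dapi, fx$assay)
  r2 <- tdp43_cyto_nuclear_ratio(fx$map2, fx$dapi, fx$assay)
  expect_identical(r1, r2)
})
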