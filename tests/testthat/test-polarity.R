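test_that("cell centre estimation: symmetry, manual echo, equal-area radius", {
  px <- 0.1
  img <- matrix(0, 64, 64)
  xs <- seq_len(64)
  img[outer((xs - 32)^2, (xs - 32)^2, `+`) <= 10^2] <- 100
  geom <- estimate_cell_center(img, px)
  expect_lt(max(abs(geom$center - c(32, 32))), 0.5)
  expect_equal(geom$source, "nucleus_auto")

  manual <- estimate_cell_center(pixel_size = px, manual = c(10, 12, 3.5))
  expect_equal(manual$center, c(10, 12))
  expect_equal(manual$radius, 3.5)
  expect_equal(manual$source, "manual_circle")

  # disk of area 400 px^2 at 0.1 um/px -> radius sqrt(400/pi)*0.1
  img2 <- matrix(0, 64, 64)
  img2[seq_len(400)] <- 50  # any 400-pixel foreground
  geom2 <- estimate_cell_center(img2, px)
  expect_equal(geom2$radius, sqrt(400 / pi) * 0.1, tolerance = 1e-12)

  expect_error(estimate_cell_center(matrix(3, 8, 8), px), "manual circle")
})

test_that("intensity centroid reproduces hand-computed weighted means", {
  px <- 0.1
  img <- matrix(0, 16, 16); img[9, 5] <- 7  # y = 9, x = 5
  expect_equal(intensity_centroid(img, px, background_radius = NULL), c(5, 9))

  img2 <- matrix(0, 16, 16); img2[3, 2] <- 4; img2[3, 12] <- 4
  expect_equal(intensity_centroid(img2, px, background_radius = NULL), c(7, 3))

  img3 <- matrix(0, 16, 16); img3[5, 2] <- 1; img3[5, 12] <- 3
  expect_equal(intensity_centroid(img3, px, background_radius = NULL)[1], 9.5)

  expect_error(intensity_centroid(matrix(0, 8, 8), px, NULL),
               "empty channel")
  expect_error(intensity_centroid(matrix(5, 64, 64), px, 2.6),
               "all intensity removed")
})

test_that("centroid of a centrally symmetric pattern is its centre", {
  px <- 0.08
  xs <- seq_len(81)
  for (sigma in c(3, 8)) {
    img <- exp(-(outer((xs - 41)^2, (xs - 41)^2, `+`)) / (2 * sigma^2))
    cen <- intensity_centroid(img, px, background_radius = NULL)
    expect_lt(max(abs(cen - c(41, 41))), 1e-6)
  }
  # ring (annulus), off-centre in the frame
  ring <- matrix(0, 81, 81)
  d2 <- outer((xs - 30)^2, (xs - 35)^2, `+`)
  ring[d2 >= 64 & d2 <= 121] <- 5
  expect_lt(max(abs(intensity_centroid(ring, px, NULL) - c(35, 30))), 1e-6)
})

test_that("asymmetry converts pixel displacement to um and respects invariances", {
  geom <- cell_geometry(c(10, 32), 3.5)
  expect_equal(asymmetry(c(10, 32), geom, 0.1), 0)
  expect_equal(asymmetry(c(13, 32), geom, 0.1), 0.3)
  expect_equal(asymmetry(c(13, 32), geom, 0.1, normalise = TRUE), 0.3 / 3.5)

  # invariance to translation and uniform intensity rescaling
  px <- 0.1
  img <- matrix(0, 64, 64); img[20:24, 30:36] <- hash_matrix(5, 7, 2) + 1
  g1 <- cell_geometry(c(30, 20), 2)
  a1 <- asymmetry(intensity_centroid(img, px, NULL), g1, px)
  shifted <- matrix(0, 64, 64); shifted[30:34, 35:41] <- img[20:24, 30:36]
  g2 <- cell_geometry(c(35, 30), 2)
  expect_equal(asymmetry(intensity_centroid(shifted, px, NULL), g2, px), a1)
  expect_equal(asymmetry(intensity_centroid(img * 7.5, px, NULL), g1, px), a1)
})

test_that("cluster half-width matches closed forms and is label-invariant", {
  px <- 0.1
  img <- matrix(0, 12, 20)
  lab1 <- matrix(0L, 12, 20); lab1[6, 4] <- 1L; img[6, 4] <- 5
  lm1 <- structure(list(labels = lab1, n_clusters = 1L, areas = 1L),
                   class = "label_map")
  expect_equal(cluster_half_width(lm1, img, px), 0)

  # two equal pixels 10 px apart on one row: SD_x = 5, SD_y = 0
  img2 <- matrix(0, 12, 20); img2[6, 4] <- 3; img2[6, 14] <- 3
  lab2 <- matrix(0L, 12, 20); lab2[6, 4] <- 1L; lab2[6, 14] <- 1L
  lm2 <- structure(list(labels = lab2, n_clusters = 1L, areas = 2L),
                   class = "label_map")
  expect_equal(cluster_half_width(lm2, img2, px), 0.25)

  # splitting the cluster into two labels leaves the value unchanged
  lab2b <- lab2; lab2b[6, 14] <- 2L
  lm2b <- structure(list(labels = lab2b, n_clusters = 2L, areas = c(1L, 1L)),
                    class = "label_map")
  expect_equal(cluster_half_width(lm2b, img2, px),
               cluster_half_width(lm2, img2, px))

  # uniform intensity rescaling invariance
  expect_equal(cluster_half_width(lm2, img2 * 13, px), 0.25)

  # no clusters -> NA marker, not zero
  lm0 <- label_clusters(matrix(FALSE, 12, 20))
  hw <- cluster_half_width(lm0, img, px)
  expect_true(is.na(hw))
  expect_equal(attr(hw, "reason"), "no clusters")
})

test_that("half-width of an isotropic Gaussian approaches its sigma", {
  px <- 0.1
  xs <- seq_len(121)
  for (sigma_px in c(4, 7, 10)) {
    img <- exp(-(outer((xs - 61)^2, (xs - 61)^2, `+`)) / (2 * sigma_px^2))
    lm <- label_clusters(img > 1e-6, min_area = 1L)  # threshold -> 0
    expect_equal(cluster_half_width(lm, img, px), sigma_px * px,
                 tolerance = 0.02)
  }
})

test_that("spot statistics match a per-cluster loop oracle", {
  px <- 0.1
  img <- matrix(0, 10, 10); img[2:3, 2:3] <- 10
  lm <- label_clusters(img > 0, min_area = 1L)
  ss <- spot_stats(lm, img, px)
  expect_equal(ss$mean_spot_intensity, 10)
  expect_equal(ss$mean_spot_area_um2, 0.04)

  img[7:8, 7:8] <- 30
  lm2 <- label_clusters(img > 0, min_area = 1L)
  expect_equal(spot_stats(lm2, img, px)$mean_spot_intensity, 20)

  # random labelled image vs explicit loop
  rimg <- hash_matrix(24, 24, 9) + 1
  mask <- hash_matrix(24, 24, 10) > 200
  lm3 <- label_clusters(mask, min_area = 1L)
  if (lm3$n_clusters > 0L) {
    means <- areas <- numeric(lm3$n_clusters)
    for (l in seq_len(lm3$n_clusters)) {
      sel <- lm3$labels == l
      means[l] <- mean(rimg[sel]); areas[l] <- sum(sel)
    }
    ss3 <- spot_stats(lm3, rimg, px)
    expect_equal(ss3$mean_spot_intensity, mean(means))
    expect_equal(ss3$mean_spot_area_um2, mean(areas) * px^2)
  }

  ss0 <- spot_stats(label_clusters(matrix(FALSE, 5, 5)), matrix(0, 5, 5), px)
  expect_true(is.na(ss0$mean_spot_intensity))
})

test_that("the polarity pipeline recovers planted truth and is deterministic", {
  scene <- scene_spec()
  cfg <- run_config(channel_roles = list(nucleus = "nucleus",
                                         compartment_a = "a"))
  # cage-like cell: asymmetry near zero
  cage <- simulate_cell(scene, list(puncta_channel_spec(
    n_puncta = 40L, placement_spread = 1.5, name = "a")),
    noise_spec(seed = 31L))
  geom <- estimate_cell_center(get_channel(cage$image, "nucleus"),
                               scene$pixel_size)
  m1 <- compute_polarity_metrics(cage$image, "a", geom, cfg)
  expect_lt(m1$asymmetry_um, 0.5)

  # 8 well-separated puncta recovered exactly
  spots8 <- simulate_cell(scene, list(puncta_channel_spec(
    n_puncta = 8L, placement_spread = 2, min_separation = 1, name = "a")),
    noise_spec(seed = 32L))
  g8 <- estimate_cell_center(get_channel(spots8$image, "nucleus"),
                             scene$pixel_size)
  m8 <- compute_polarity_metrics(spots8$image, "a", g8, cfg)
  expect_equal(m8$cluster_count, 8L)
  expect_gt(m8$half_width_um, 0)
  expect_true(m8$area_coverage >= 0 && m8$area_coverage <= 1)

  # determinism
  m8b <- compute_polarity_metrics(spots8$image, "a", g8, cfg)
  expect_identical(m8[names(m8) != "params"], m8b[names(m8b) != "params"])
})

test_that("polarised/cage classification uses a strict threshold", {
  expect_false(classify_polarised(0, 0.5))
  expect_false(classify_polarised(0.5, 0.5))  # tie -> not polarised
  expect_true(classify_polarised(0.51, 0.5))
  expect_error(classify_polarised(NA_real_, 0.5), "undefined")

  # synthetic two-population benchmark, midpoint threshold
  scene <- scene_spec()
  cfg <- run_config(channel_roles = list(nucleus = "nucleus",
                                         compartment_a = "a"))
  measure <- function(offset, seeds) vapply(seeds, function(s) {
    cell <- simulate_cell(scene, list(puncta_channel_spec(
      n_puncta = 40L, polarisation_offset = offset,
      placement_spread = 0.5, name = "a")), noise_spec(seed = s),
      keep_noiseless = FALSE)
    geom <- estimate_cell_center(get_channel(cell$image, "nucleus"),
                                 scene$pixel_size)
    compute_polarity_metrics(cell$image, "a", geom, cfg)$asymmetry_um
  }, 0)
  a0 <- measure(0, 1:20)
  a2 <- measure(2, 21:40)
  thr <- (mean(a0) + mean(a2)) / 2
  acc <- (sum(!vapply(a0, classify_polarised, TRUE, thr)) +
          sum(vapply(a2, classify_polarised, TRUE, thr))) / 40
  expect_gte(acc, 0.95)
})

test_that("nucleus-derived geometry is inflated to cell size, manual is not", {
  cfg <- run_config(cell_mask_scale = 1.25)
  auto <- cell_geometry(c(10, 10), 2, source = "nucleus_auto")
  expect_equal(effective_geometry(auto, cfg)$radius, 2.5)
  man <- cell_geometry(c(10, 10), 2, source = "manual_circle")
  expect_equal(effective_geometry(man, cfg)$radius, 2)
})
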