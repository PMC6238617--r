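test_that("simulation is deterministic under a fixed seed", {
  scene <- tiny_scene()
  chs <- list(puncta_channel_spec(n_puncta = 15L, placement_spread = 1.2,
                                  name = "a"))
  c1 <- simulate_cell(scene, chs, noise_spec(seed = 11L))
  c2 <- simulate_cell(scene, chs, noise_spec(seed = 11L))
  expect_identical(c1$image$channels, c2$image$channels)
  expect_identical(c1$truth, c2$truth)
  c3 <- simulate_cell(scene, chs, noise_spec(seed = 12L))
  expect_false(identical(c1$image$channels, c3$image$channels))
})

test_that("an empty puncta channel is background plus noise only", {
  scene <- tiny_scene(cell_radius = 3.5, nucleus_radius = 1.5,
                      background_level = 10)
  chs <- list(puncta_channel_spec(n_puncta = 0L, placement_spread = 1,
                                  name = "a"))
  cell <- simulate_cell(scene, chs, quiet_noise())
  expect_true(all(get_channel(cell$image, "a") == 10))
  expect_equal(cell$truth$true_cluster_count, 0L)

  # with noise the channel stays statistically at background level
  celln <- simulate_cell(scene, chs, noise_spec(seed = 3L))
  expect_lt(abs(mean(get_channel(celln$image, "a")) - 10), 1)
})

test_that("spot centres average to the distribution centre (placement oracle)", {
  scene <- scene_spec()  # default 128 px frame fits spread 2 um
  chs <- list(puncta_channel_spec(n_puncta = 200L, polarisation_offset = 0,
                                  placement_spread = 2, name = "a"))
  cell <- simulate_cell(scene, chs, noise_spec(seed = 5L))
  centroid <- colMeans(cell$spots[["a"]])
  tol_px <- 3 * (2 / 0.08) / sqrt(200)
  expect_lt(sqrt(sum((centroid - scene$cell_center)^2)), tol_px)
  expect_equal(cell$truth$true_asymmetry, 0)
  expect_equal(cell$truth$true_centroid_per_channel[["a"]], centroid)
})

test_that("planted polarisation values are echoed in the ground truth", {
  scene <- tiny_scene()
  chs <- list(puncta_channel_spec(polarisation_offset = 2.0,
                                  placement_spread = 0.5, name = "a"))
  cell <- simulate_cell(scene, chs, noise_spec(seed = 2L))
  expect_equal(cell$truth$true_asymmetry, 2.0)
  expect_equal(cell$truth$true_cluster_count, 40L)
  # all spots inside the cell disk
  d <- sqrt(rowSums(sweep(cell$spots[["a"]], 2, scene$cell_center)^2))
  expect_true(all(d <= scene$cell_radius / scene$pixel_size + 1e-9))
})

test_that("noiseless channel intensity is conserved within 1%", {
  scene <- scene_spec(background_level = 0)
  for (s in c(1, 2)) {
    ch <- puncta_channel_spec(n_puncta = 30L, puncta_sigma = 0.12,
                              amplitude = 150, placement_spread = 1.2,
                              name = "a")
    cell <- simulate_cell(scene, list(ch), quiet_noise(s))
    total <- sum(cell$noiseless[["a"]])
    expected <- 30 * 150 * 2 * pi * (0.12 / 0.08)^2
    expect_lt(abs(total - expected) / expected, 0.01)
  }
})

test_that("planted offset strictly increases the noiseless centroid shift", {
  scene <- scene_spec()
  shift_for <- function(offset, seeds) {
    mean(vapply(seeds, function(s) {
      ch <- puncta_channel_spec(n_puncta = 40L, polarisation_offset = offset,
                                placement_spread = 0.5, name = "a")
      cell <- simulate_cell(scene, list(ch), quiet_noise(s),
                            keep_noiseless = TRUE)
      m <- cell$noiseless[["a"]] - scene$background_level
      xs <- matrix(seq_len(ncol(m)), nrow(m), ncol(m), byrow = TRUE)
      ys <- matrix(seq_len(nrow(m)), nrow(m), ncol(m))
      cx <- sum(xs * m) / sum(m); cy <- sum(ys * m) / sum(m)
      sqrt((cx - scene$cell_center[1])^2 + (cy - scene$cell_center[2])^2)
    }, 0))
  }
  seeds <- 1:50
  shifts <- vapply(c(0, 1, 2), shift_for, 0, seeds = seeds)
  expect_true(all(diff(shifts) > 0))
})

test_that("impossible placement constraints raise a named error", {
  scene <- tiny_scene()
  bad <- puncta_channel_spec(n_puncta = 100L, placement_spread = 0.4,
                             min_separation = 1.5, name = "crowded")
  expect_error(simulate_cell(scene, list(bad), noise_spec(seed = 1L)),
               "crowded")
  # invariant violation caught before sampling
  off <- puncta_channel_spec(polarisation_offset = 3, placement_spread = 1,
                             name = "far")
  expect_error(simulate_cell(scene, list(off), noise_spec(seed = 1L)),
               "exceeds the cell radius")
})

test_that("channel overlap reuses spot centres and is recorded", {
  scene <- tiny_scene()
  chs <- list(puncta_channel_spec(n_puncta = 20L, placement_spread = 1.2,
                                  name = "a"),
              puncta_channel_spec(n_puncta = 20L, placement_spread = 1.2,
                                  name = "b"))
  for (f in c(0, 0.5, 1)) {
    cell <- simulate_cell(scene, chs, noise_spec(seed = 4L),
                          overlap_fraction = f)
    shared <- sum(cell$spots[["b"]][, 1] %in% cell$spots[["a"]][, 1])
    expect_equal(shared, round(f * 20))
    expect_equal(cell$truth$true_overlap_fraction, f)
  }
})

test_that("population simulation is deterministic and stratified", {
  scene <- tiny_scene()
  chs <- list(puncta_channel_spec(n_puncta = 10L, placement_spread = 1.2,
                                  name = "a"))
  p1 <- simulate_population(10L, scene, chs, master_seed = 21L,
                            offsets = c(0, 2))
  p2 <- simulate_population(10L, scene, chs, master_seed = 21L,
                            offsets = c(0, 2))
  expect_identical(p1$ground_truth, p2$ground_truth)
  expect_identical(p1$cells[[3L]]$image$channels,
                   p2$cells[[3L]]$image$channels)
  expect_equal(sum(p1$ground_truth$true_asymmetry_um == 0), 5L)
  expect_equal(sum(p1$ground_truth$true_asymmetry_um == 2), 5L)

  expect_error(simulate_population(0L, scene, chs), "n_cells")
  expect_error(simulate_population(2L, scene, chs, offsets = -1), "offsets")
  expect_error(simulate_population(2L, scene, chs, overlap_fractions = 2),
               "overlap_fractions")
})

test_that("a population round-trips through TIFF and CSV", {
  scene <- tiny_scene()
  chs <- list(puncta_channel_spec(n_puncta = 8L, placement_spread = 1.2,
                                  name = "a"))
  pop <- simulate_population(3L, scene, chs, master_seed = 8L)
  dir <- withr::local_tempdir()
  write_population(pop, dir)
  expect_length(list.files(dir, pattern = "\\.tif$"), 3L)
  gt <- utils::read.csv(file.path(dir, "ground_truth.csv"))
  expect_equal(nrow(gt), 3L)
  back <- read_image(file.path(dir, gt$file[2L]))
  expect_identical(back$channels, pop$cells[[2L]]$image$channels)
})
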