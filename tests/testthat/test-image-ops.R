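test_that("max projection matches an explicit per-pixel loop", {
  # single slice: identity
  m <- hash_matrix(8, 9, 1)
  img1 <- multichannel_image(list(a = m), 0.1)
  expect_equal(get_channel(max_project(img1), "a"), m)

  # two slices, values 3 and 7 at the same position
  arr <- array(0, c(2, 4, 4)); arr[1, 2, 3] <- 3; arr[2, 2, 3] <- 7
  proj <- max_project(multichannel_image(list(a = arr), 0.1))
  expect_equal(get_channel(proj, "a")[2, 3], 7)

  # random 5-slice stack vs brute-force loop oracle
  arr <- array(hash_matrix(5 * 12, 10, 3), c(5, 12, 10))
  proj <- get_channel(max_project(multichannel_image(list(a = arr), 0.1)), "a")
  oracle <- matrix(0, 12, 10)
  for (y in 1:12) for (x in 1:10) oracle[y, x] <- max(arr[, y, x])
  expect_equal(proj, oracle)
})

test_that("bandpass annihilates constants exactly and is linear", {
  const <- matrix(7.3, 40, 40)
  resp <- bandpass(const, filter_band(0.13, 0.9), 0.08, clip = FALSE)
  expect_true(all(resp == 0))

  x <- hash_matrix(40, 40, 11) / 10
  y <- hash_matrix(40, 40, 12) / 10
  band <- filter_band(0.13, 0.9)
  lhs <- bandpass(2.5 * x + 0.7 * y, band, 0.08, clip = FALSE)
  rhs <- 2.5 * bandpass(x, band, 0.08, clip = FALSE) +
    0.7 * bandpass(y, band, 0.08, clip = FALSE)
  expect_lt(max(abs(lhs - rhs)) / max(abs(rhs)), 1e-8)
})

test_that("bandpass response to a point source follows the DoG kernel", {
  px <- 0.1
  band <- filter_band(0.2, 1.0)
  img <- matrix(0, 41, 41); img[21, 21] <- 1
  resp <- bandpass(img, band, px, clip = FALSE)
  # closed-form 2D DoG evaluated at integer offsets (kernels renormalised
  # over the same truncated support the implementation uses)
  dog_at <- function(d) {
    g <- function(sigma) {
      r <- max(1L, ceiling(4 * sigma)); xs <- (-r):r
      k <- exp(-xs^2 / (2 * sigma^2)); k <- k / sum(k)
      k1 <- k[match(0, xs) + d]
      k0 <- k[match(0, xs)]
      k1 * k0  # separable: offset along one axis only
    }
    g(band$low_scale / (2 * px)) - g(band$high_scale / (2 * px))
  }
  for (d in 0:2)
    expect_equal(resp[21, 21 + d], dog_at(d), tolerance = 1e-10)
  # maximal at the source, decreasing outward
  expect_equal(resp[21, 21], max(resp))
  expect_true(resp[21, 21] > resp[21, 22])
  expect_true(resp[21, 22] > resp[21, 23])
})

test_that("bandpass favours in-band spots over coarse blobs", {
  px <- 0.1
  xs <- seq_len(81)
  spot <- exp(-(outer((xs - 20)^2, (xs - 20)^2, `+`)) / (2 * (0.3 / 2 / px)^2))
  blob <- exp(-(outer((xs - 60)^2, (xs - 60)^2, `+`)) / (2 * (5 / 2 / px)^2))
  img <- spot + blob
  before <- max(img[1:40, 1:40]) / max(img[41:81, 41:81])
  resp <- bandpass(img, filter_band(0.13, 0.9), px, clip = FALSE)
  after <- max(resp[1:40, 1:40]) / max(resp[41:81, 41:81])
  expect_gt(after, before)
})

test_that("bandpass rejects invalid bands and oversized scales", {
  expect_error(filter_band(0.9, 0.13), "low_scale")
  expect_error(filter_band(0, 1), "low_scale")
  expect_error(bandpass(matrix(1:16 / 4, 4, 4), filter_band(0.13, 0.9), 0.08),
               "extent")
})

test_that("local background subtraction removes pedestals, keeps spots", {
  px <- 0.1
  # constant image -> all zeros
  expect_true(all(subtract_local_background(matrix(5, 60, 60), 2.6, px) == 0))
  # all-zero image -> all zeros
  expect_true(all(subtract_local_background(matrix(0, 60, 60), 2.6, px) == 0))

  # isolated Gaussian spot (sigma 0.2 um) on pedestal 100
  xs <- seq_len(80)
  spot <- 50 * exp(-(outer((xs - 40)^2, (xs - 40)^2, `+`)) / (2 * (0.2 / px)^2))
  img <- spot + 100
  for (method in c("opening", "median")) {
    sub <- subtract_local_background(img, 2.6, px, method = method)
    expect_lt(abs(max(sub) - 50) / 50, 0.05)
    expect_lt(max(sub[1:10, 1:10]), 1e-6)  # pedestal gone far from the spot
    expect_true(all(sub <= img + 1e-12))   # anti-extensive
    expect_true(all(sub >= 0))
  }
})

test_that("oversized background radius falls back to global minimum", {
  img <- matrix(c(3, 4, 5, 6), 10, 10)
  expect_warning(sub <- subtract_local_background(img, 50, 0.1), "half-extent")
  expect_equal(sub, pmax(img - 3, 0))
})

test_that("otsu matches the exhaustive between-class-variance maximiser", {
  # perfectly bimodal
  v <- c(rep(0, 50), rep(10, 50))
  t <- otsu_threshold(matrix(v, 10, 10))
  expect_true(t > 0 && t < 10)

  # random 8-bit images vs brute-force oracle (partition equality)
  for (s in 1:10) {
    m <- hash_matrix(32, 32, s)
    t <- otsu_threshold(m, 256L)
    cut <- otsu_oracle_split(as.numeric(m))
    expect_identical(m <= t, m <= cut)
  }

  # two well-separated Gaussian modes are fully split
  set.seed(99)
  v <- c(rnorm(300, 20, 2), rnorm(300, 200, 2))
  t <- otsu_threshold(matrix(v, 60, 10))
  expect_true(all(v[1:300] < t) && all(v[301:600] > t))

  expect_error(otsu_threshold(matrix(1, 5, 5)), "constant")
})

test_that("cluster labeling obeys connectivity, min_area and renumbering", {
  expect_equal(label_clusters(matrix(FALSE, 5, 5))$n_clusters, 0L)

  m <- matrix(FALSE, 10, 10)
  m[2:4, 2:4] <- TRUE; m[7:9, 7:9] <- TRUE
  expect_equal(label_clusters(m)$n_clusters, 2L)

  # diagonal touch: one component under 8-connectivity, two under 4
  d <- matrix(FALSE, 6, 6); d[2, 2] <- TRUE; d[3, 3] <- TRUE
  expect_equal(label_clusters(d, min_area = 1L, connectivity = 8L)$n_clusters, 1L)
  expect_equal(label_clusters(d, min_area = 1L, connectivity = 4L)$n_clusters, 2L)

  # min_area discards small components and renumbers consecutively
  m[6, 1] <- TRUE  # single-pixel speck
  lm <- label_clusters(m, min_area = 4L)
  expect_equal(lm$n_clusters, 2L)
  expect_setequal(unique(as.integer(lm$labels)), c(0L, 1L, 2L))
  expect_equal(lm$areas, c(9L, 9L))
})

test_that("cluster count is translation invariant away from borders", {
  base <- matrix(FALSE, 20, 20)
  base[3:5, 3:4] <- TRUE; base[10:11, 12:14] <- TRUE; base[15, 7:9] <- TRUE
  n0 <- label_clusters(base, min_area = 1L)$n_clusters
  for (shift in list(c(2, 3), c(4, 0), c(0, 5))) {
    moved <- matrix(FALSE, 20, 20)
    idx <- which(base, arr.ind = TRUE)
    moved[cbind(idx[, 1] + shift[1], idx[, 2] + shift[2])] <- TRUE
    expect_equal(label_clusters(moved, min_area = 1L)$n_clusters, n0)
  }
})

test_that("area coverage counts masked pixels above threshold", {
  img <- matrix(1, 10, 10)
  expect_equal(area_coverage(img, 0), 1.0)
  expect_equal(area_coverage(img, 2), 0.0)
  img2 <- matrix(0, 10, 10); img2[1:5, 1:5] <- 3
  expect_equal(area_coverage(img2, 1), 0.25)
  mask <- matrix(FALSE, 10, 10)
  expect_error(area_coverage(img2, 1, mask), "empty mask")
})
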