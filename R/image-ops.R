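#' Spatial-scale band for bandpass filtering
#'
#' Holds the physical scale band of the spot-enhancement filter. The default
#' values (0.13 to 0.9 micrometres) bracket diffraction-limited puncta as
#' imaged on a high-NA confocal: structures smaller than `low_scale` are
#' treated as noise, structures larger than `high_scale` as background.
#'
#' @param low_scale lower spatial scale, um (> 0)
#' @param high_scale upper spatial scale, um (> low_scale)
#' @return an object of class `filter_band`
#' @export
filter_band <- function(low_scale = 0.13, high_scale = 0.9) {
  if (!is.numeric(low_scale) || !is.numeric(high_scale) ||
      length(low_scale) != 1L || length(high_scale) != 1L ||
      !is.finite(low_scale) || !is.finite(high_scale) ||
      low_scale <= 0 || high_scale <= low_scale)
    stop("filter band requires 0 < low_scale < high_scale (um)")
  structure(list(low_scale = low_scale, high_scale = high_scale),
            class = "filter_band")
}

.gaussian_kernel_1d <- function(sigma) {
  r <- max(1L, as.integer(ceiling(4 * sigma)))
  x <- (-r):r
  k <- exp(-x^2 / (2 * sigma^2))
  k / sum(k)
}

# separable convolution along rows (y) with symmetric boundary padding
.conv_rows <- function(m, k) {
  r <- (length(k) - 1L) %/% 2L
  n <- nrow(m)
  if (r >= n) stop("kernel radius exceeds image extent")
  mp <- rbind(m[r:1, , drop = FALSE], m, m[n:(n - r + 1L), , drop = FALSE])
  out <- matrix(0, n, ncol(m))
  for (o in seq_along(k))
    out <- out + k[o] * mp[o:(o + n - 1L), , drop = FALSE]
  out
}

#' Gaussian blur with a physically sized kernel
#'
#' Separable Gaussian smoothing with symmetric (mirror) boundary handling,
#' which preserves constant images.
#'
#' @param img numeric matrix
#' @param sigma Gaussian standard deviation in pixels
#' @return blurred matrix of the same shape
#' @export
gaussian_blur <- function(img, sigma) {
  stopifnot(is.matrix(img), is.numeric(sigma), sigma > 0)
  k <- .gaussian_kernel_1d(sigma)
  t(.conv_rows(t(.conv_rows(img, k)), k))
}

#' Difference-of-Gaussians bandpass at physical scales
#'
#' Enhances structures between `band$low_scale` and `band$high_scale`
#' micrometres by subtracting a coarse Gaussian blur from a fine one.
#' Scales map to Gaussian sigmas as `sigma = scale / (2 * pixel_size)`
#' pixels by default (`sigma_rule = "half"`); `"fwhm"` uses the
#' full-width-at-half-maximum convention `scale / (2.355 * pixel_size)`.
#'
#' The image is centred on its first pixel value before filtering; a
#' difference of two unit-sum kernels annihilates constants, so this leaves
#' the response unchanged in exact arithmetic while making the all-constant
#' case exactly zero in floating point.
#'
#' @param img numeric matrix of intensities
#' @param band a [filter_band()]
#' @param pixel_size um per pixel
#' @param clip clip negative responses to zero (default `TRUE`); set
#'   `FALSE` to obtain the raw linear response
#' @param sigma_rule `"half"` (sigma = scale/2) or `"fwhm"` (scale/2.355)
#' @return filtered matrix of the same shape
#' @export
bandpass <- function(img, band, pixel_size, clip = TRUE,
                     sigma_rule = c("half", "fwhm")) {
  stopifnot(is.matrix(img), inherits(band, "filter_band"),
            is.numeric(pixel_size), pixel_size > 0)
  sigma_rule <- match.arg(sigma_rule)
  den <- if (sigma_rule == "half") 2 else 2.355
  s_low <- band$low_scale / (den * pixel_size)
  s_high <- band$high_scale / (den * pixel_size)
  if (ceiling(4 * s_high) >= min(dim(img)))
    stop("high_scale too large for this image extent at this pixel size")
  centred <- img - img[1L]
  resp <- gaussian_blur(centred, s_low) - gaussian_blur(centred, s_high)
  if (clip) pmax(resp, 0) else resp
}

.disk_offsets <- function(radius_px) {
  r <- as.integer(ceiling(radius_px))
  g <- expand.grid(dy = -r:r, dx = -r:r)
  g <- g[g$dy^2 + g$dx^2 <= radius_px^2, , drop = FALSE]
  g
}

#' Subtract a locally estimated background
#'
#' Estimates the background as the greyscale morphological opening of the
#' image by a flat disk of the given physical radius (rolling-ball-like) and
#' subtracts it, clipping at zero. Structures narrower than the disk (the
#' puncta of interest) do not survive the opening and are therefore
#' preserved by the subtraction; smooth pedestals are removed. The default
#' radius used by the polarity pipeline is 2.6 um.
#'
#' @param img numeric matrix
#' @param radius disk radius, um
#' @param pixel_size um per pixel
#' @param method `"opening"` (default) or `"median"` (local median over the
#'   same disk; unbiased on noisy flat background, preferred by the
#'   centroid estimator)
#' @return background-subtracted matrix, elementwise `<=` the input and
#'   `>= 0`
#' @export
subtract_local_background <- function(img, radius, pixel_size,
                                      method = c("opening", "median")) {
  bg <- local_background(img, radius, pixel_size, method = method)
  pmax(img - bg, 0)
}

#' Local background estimate
#'
#' The background field that [subtract_local_background()] removes:
#' either the greyscale opening of the image by a flat disk of the given
#' radius, or the local median over the same disk (Huang sliding-histogram
#' filter, intensities quantised to 2048 bins). The opening sits at the
#' local noise floor (it is bounded by the window minimum), while the
#' median is an unbiased level estimate under symmetric noise; both ignore
#' structures narrower than the disk.
#'
#' @inheritParams subtract_local_background
#' @return matrix of background estimates
#' @export
local_background <- function(img, radius, pixel_size,
                             method = c("opening", "median")) {
  stopifnot(is.matrix(img), is.numeric(radius), radius > 0,
            is.numeric(pixel_size), pixel_size > 0)
  method <- match.arg(method)
  r_px <- radius / pixel_size
  if (r_px < 1)
    stop("background radius is below one pixel at this pixel size")
  if (r_px > min(dim(img)) / 2) {
    warning("background radius exceeds the image half-extent; ",
            "using the global minimum as background")
    return(matrix(min(img), nrow(img), ncol(img)))
  }
  if (method == "opening") {
    off <- .disk_offsets(r_px)
    eroded <- cpp_grey_morph(img, off$dy, off$dx, TRUE)
    cpp_grey_morph(eroded, off$dy, off$dx, FALSE)
  } else {
    cpp_disk_median(img, r_px, 2048L)
  }
}

#' Otsu's threshold
#'
#' Histogram threshold maximising the between-class variance over an
#' `n_bins` equal-width histogram spanning the intensity range. The
#' returned value is the bin edge; ties are broken towards the lower
#' threshold. Pixels strictly above the threshold form the foreground.
#'
#' @param img numeric matrix (or vector) with at least two distinct values
#' @param n_bins number of histogram bins (default 256)
#' @return the threshold intensity (a single number)
#' @export
otsu_threshold <- function(img, n_bins = 256L) {
  v <- as.numeric(img)
  v <- v[is.finite(v)]
  if (length(v) < 2L) stop("need at least two pixels to threshold")
  rng <- range(v)
  if (rng[1L] == rng[2L])
    stop("constant image: Otsu threshold undefined")
  n_bins <- as.integer(n_bins)
  stopifnot(n_bins >= 2L)
  w <- (rng[2L] - rng[1L]) / n_bins
  idx <- pmin(floor((v - rng[1L]) / w), n_bins - 1L)  # 0-based bin index
  counts <- tabulate(idx + 1L, n_bins)
  p <- counts / length(v)
  # exact per-bin intensity sums: class means are then true means, so the
  # binned maximiser coincides with the exhaustive one whenever distinct
  # values do not share a bin (always true for 8-bit data at 256 bins)
  bin_sums <- numeric(n_bins)
  rs <- rowsum(v, idx)
  bin_sums[as.integer(rownames(rs)) + 1L] <- rs
  w0 <- cumsum(p)
  mu_cum <- cumsum(bin_sums / length(v))
  mu_t <- mu_cum[n_bins]
  k <- seq_len(n_bins - 1L)
  w0k <- w0[k]
  w1k <- 1 - w0k
  sigma_b <- rep(-Inf, n_bins - 1L)
  valid <- w0k > 0 & w1k > 0
  mu0 <- mu_cum[k][valid] / w0k[valid]
  mu1 <- (mu_t - mu_cum[k][valid]) / w1k[valid]
  sigma_b[valid] <- w0k[valid] * w1k[valid] * (mu0 - mu1)^2
  kstar <- which.max(sigma_b)  # first maximum: lower threshold on ties
  rng[1L] + kstar * w
}

#' Label connected clusters in a binary mask
#'
#' Connected-component labeling (8-connectivity by default, so
#' diagonal-touching pixels join one cluster), with components smaller than
#' `min_area` pixels discarded and the survivors renumbered consecutively
#' in scan order.
#'
#' @param mask logical matrix (`TRUE` = foreground)
#' @param min_area minimum component area in pixels (default 4, suppressing
#'   single-pixel noise)
#' @param connectivity 4 or 8 (default 8)
#' @return an object of class `label_map`: list with `labels` (integer
#'   matrix, 0 = background), `n_clusters`, and `areas` (pixel counts per
#'   cluster)
#' @export
label_clusters <- function(mask, min_area = 4L, connectivity = 8L) {
  stopifnot(is.matrix(mask))
  if (!is.logical(mask)) mask <- mask > 0
  connectivity <- as.integer(connectivity)
  if (!connectivity %in% c(4L, 8L)) stop("connectivity must be 4 or 8")
  lab <- cpp_label_components(mask, connectivity)
  n0 <- max(lab)
  if (n0 > 0L && min_area > 1L) {
    areas <- tabulate(lab[lab > 0L], n0)
    keep <- which(areas >= min_area)
    remap <- integer(n0)
    remap[keep] <- seq_along(keep)
    pos <- lab > 0L
    lab[pos] <- remap[lab[pos]]
  }
  n <- max(lab)
  areas <- if (n > 0L) tabulate(lab[lab > 0L], n) else integer(0)
  structure(list(labels = lab, n_clusters = n, areas = areas),
            class = "label_map")
}

#' @export
print.label_map <- function(x, ...) {
  cat(sprintf("<label_map> %d cluster(s) over %d x %d px\n",
              x$n_clusters, nrow(x$labels), ncol(x$labels)))
  invisible(x)
}

#' Fraction of (masked) pixels above a threshold
#'
#' Area coverage of a channel: the fraction of pixels with intensity
#' strictly above `threshold`. When a cell mask is supplied, the
#' denominator is the mask area; otherwise the whole crop.
#'
#' @param img numeric matrix
#' @param threshold intensity threshold (finite)
#' @param mask optional logical matrix selecting the in-cell pixels
#' @return a fraction in `[0, 1]`
#' @export
area_coverage <- function(img, threshold, mask = NULL) {
  stopifnot(is.matrix(img), is.numeric(threshold), is.finite(threshold))
  v <- if (is.null(mask)) as.numeric(img) else {
    stopifnot(is.logical(mask), identical(dim(mask), dim(img)))
    img[mask]
  }
  if (length(v) == 0L) stop("empty mask: area coverage undefined")
  mean(v > threshold)
}
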