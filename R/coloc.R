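#' Crop an image to the cell circle
#'
#' Rectangular crop covering the cell circle plus `padding` um, clamped to
#' the image bounds; the geometry is re-expressed in crop coordinates.
#'
#' @param image a [multichannel_image()]
#' @param geometry a [cell_geometry()]
#' @param padding extra margin around the circle, um (default 0)
#' @return list with `image` (cropped) and `geometry` (shifted)
#' @export
crop_to_cell <- function(image, geometry, padding = 0) {
  stopifnot(inherits(image, "multichannel_image"),
            inherits(geometry, "cell_geometry"), padding >= 0)
  px <- image$pixel_size
  d <- dim(image$channels[[1L]])
  r_px <- (geometry$radius + padding) / px
  x0 <- max(1L, floor(geometry$center[1L] - r_px))
  x1 <- min(d[3L], ceiling(geometry$center[1L] + r_px))
  y0 <- max(1L, floor(geometry$center[2L] - r_px))
  y1 <- min(d[2L], ceiling(geometry$center[2L] + r_px))
  if (x1 - x0 < 3L || y1 - y0 < 3L)
    stop("degenerate crop (smaller than 4 x 4 px)")
  channels <- lapply(image$channels, function(ch)
    ch[, y0:y1, x0:x1, drop = FALSE])
  geom <- cell_geometry(geometry$center - c(x0 - 1L, y0 - 1L),
                        geometry$radius, source = geometry$source)
  list(image = multichannel_image(channels, px, image$channel_names),
       geometry = geom)
}

#' Pearson correlation between two channels
#'
#' Sample Pearson correlation of paired pixel intensities over the masked
#' pixels. Invariant to affine rescaling of either channel with positive
#' gain.
#'
#' @param chan_a,chan_b numeric matrices of identical shape
#' @param mask optional logical matrix selecting pixels (default: all)
#' @return correlation in `[-1, 1]`, or `NA` with a `reason` attribute when
#'   a channel is constant on the mask
#' @export
pearson <- function(chan_a, chan_b, mask = NULL) {
  stopifnot(is.matrix(chan_a), is.matrix(chan_b),
            identical(dim(chan_a), dim(chan_b)))
  if (is.null(mask)) {
    va <- as.numeric(chan_a); vb <- as.numeric(chan_b)
  } else {
    stopifnot(is.logical(mask), identical(dim(mask), dim(chan_a)))
    va <- chan_a[mask]; vb <- chan_b[mask]
  }
  if (length(va) < 2L)
    return(structure(NA_real_, reason = "fewer than 2 masked pixels"))
  if (stats::var(va) == 0 || stats::var(vb) == 0)
    return(structure(NA_real_, reason = "constant channel on mask"))
  stats::cor(va, vb)
}

.tls_fit <- function(va, vb) {
  saa <- stats::var(va); sbb <- stats::var(vb); sab <- stats::cov(va, vb)
  if (sab <= 0)
    stop("channels anti-correlated; Costes thresholds undefined")
  slope <- (sbb - saa + sqrt((sbb - saa)^2 + 4 * sab^2)) / (2 * sab)
  list(slope = slope, intercept = mean(vb) - slope * mean(va))
}

#' Costes automatic colocalisation thresholds
#'
#' Fits the inter-channel regression (orthogonal / total least squares by
#' default, as in the original automatic-threshold method) and walks the
#' candidate threshold `t_a` downward from the channel-A maximum, with
#' `t_b = slope * t_a + intercept`, returning the highest `t_a` at which
#' the Pearson correlation of the jointly-below-threshold pixels
#' (`a < t_a` and `b < t_b`) first drops to <= 0. Candidates are the sorted
#' unique channel-A intensities, evenly subsampled to at most
#' `max_candidates` levels, which makes the search deterministic and
#' scale-equivariant (doubling both channels doubles both thresholds).
#'
#' When the below-threshold correlation never reaches 0 (e.g. perfectly
#' proportional channels) the minimum intensity is returned with
#' `degenerate = TRUE`.
#'
#' @param chan_a,chan_b numeric matrices of identical shape
#' @param mask optional logical matrix selecting pixels
#' @param regression `"tls"` (orthogonal, default) or `"ols"`
#' @param max_candidates cap on threshold candidates (default 512)
#' @return list with `t_a`, `t_b`, `slope`, `intercept`, `degenerate`,
#'   and `r_below` (the below-threshold correlation actually achieved)
#' @export
costes_thresholds <- function(chan_a, chan_b, mask = NULL,
                              regression = c("tls", "ols"),
                              max_candidates = 512L) {
  stopifnot(is.matrix(chan_a), is.matrix(chan_b),
            identical(dim(chan_a), dim(chan_b)))
  regression <- match.arg(regression)
  if (is.null(mask)) {
    va <- as.numeric(chan_a); vb <- as.numeric(chan_b)
  } else {
    stopifnot(is.logical(mask), identical(dim(mask), dim(chan_a)))
    va <- chan_a[mask]; vb <- chan_b[mask]
  }
  if (length(va) < 4L) stop("too few masked pixels for threshold search")
  fit <- if (regression == "tls") .tls_fit(va, vb) else {
    sab <- stats::cov(va, vb)
    if (sab <= 0)
      stop("channels anti-correlated; Costes thresholds undefined")
    slope <- sab / stats::var(va)
    list(slope = slope, intercept = mean(vb) - slope * mean(va))
  }
  cand <- sort(unique(va), decreasing = TRUE)
  if (length(cand) > max_candidates)
    cand <- cand[unique(round(seq(1L, length(cand),
                                  length.out = max_candidates)))]
  for (t_a in cand) {
    t_b <- fit$slope * t_a + fit$intercept
    sel <- va < t_a & vb < t_b
    n <- sum(sel)
    if (n < 2L) next
    sa <- va[sel]; sb <- vb[sel]
    if (stats::var(sa) == 0 || stats::var(sb) == 0) next
    r <- stats::cor(sa, sb)
    if (r <= 0)
      return(list(t_a = t_a, t_b = t_b, slope = fit$slope,
                  intercept = fit$intercept, degenerate = FALSE,
                  r_below = r))
  }
  t_a <- min(va)
  list(t_a = t_a, t_b = fit$slope * t_a + fit$intercept,
       slope = fit$slope, intercept = fit$intercept,
       degenerate = TRUE, r_below = NA_real_)
}

#' Manders overlap coefficients
#'
#' `M1` is the fraction of channel-A intensity lying on pixels where
#' channel B exceeds its threshold; `M2` symmetrically for channel B over
#' the channel-A threshold.
#'
#' @param chan_a,chan_b numeric matrices of identical shape
#' @param t_a,t_b intensity thresholds (typically from
#'   [costes_thresholds()])
#' @param mask optional logical matrix selecting pixels
#' @return list with `m1` and `m2`, each in `[0, 1]` or `NA` with a
#'   `reason` attribute when the corresponding denominator is zero
#' @export
manders <- function(chan_a, chan_b, t_a, t_b, mask = NULL) {
  stopifnot(is.matrix(chan_a), is.matrix(chan_b),
            identical(dim(chan_a), dim(chan_b)),
            is.numeric(t_a), is.numeric(t_b))
  if (is.null(mask)) {
    va <- as.numeric(chan_a); vb <- as.numeric(chan_b)
  } else {
    stopifnot(is.logical(mask), identical(dim(mask), dim(chan_a)))
    va <- chan_a[mask]; vb <- chan_b[mask]
  }
  m1 <- if (sum(va) > 0) sum(va[vb > t_b]) / sum(va)
        else structure(NA_real_, reason = "zero channel-A intensity")
  m2 <- if (sum(vb) > 0) sum(vb[va > t_a]) / sum(vb)
        else structure(NA_real_, reason = "zero channel-B intensity")
  list(m1 = m1, m2 = m2)
}

#' Colocalisation report for one cell
#'
#' Chains crop -> Costes automatic thresholds -> Pearson and Manders over
#' the in-cell pixels. Two Pearson values are emitted: over all in-cell
#' pixels (`pearson_r`, the default reported statistic) and restricted to
#' pixels above both Costes thresholds (`pearson_r_above`). Manders M1/M2
#' use the Costes thresholds (the reference analysis states no separate
#' Manders thresholds; this assumption is flagged in the report).
#'
#' @param image a [multichannel_image()] (projected internally if a stack)
#' @param geometry a [cell_geometry()]
#' @param chan_a,chan_b channel names or indices to compare
#' @param config a [run_config()]; `coloc_mask` chooses the cell circle
#'   (default) or the full crop, `coloc_regression` the regression flavour
#' @return an object of class `coloc_report`
#' @export
colocalise_cell <- function(image, geometry, chan_a, chan_b,
                            config = run_config()) {
  stopifnot(inherits(image, "multichannel_image"),
            inherits(geometry, "cell_geometry"),
            inherits(config, "run_config"))
  geometry <- effective_geometry(geometry, config)
  img2 <- if (n_slices(image) > 1L) max_project(image) else image
  cropped <- crop_to_cell(img2, geometry, padding = config$crop_padding)
  a <- get_channel(cropped$image, chan_a)
  b <- get_channel(cropped$image, chan_b)
  px <- cropped$image$pixel_size
  mask <- if (identical(config$coloc_mask, "cell_circle"))
    cell_mask(cropped$geometry, dim(a), px)
  else matrix(TRUE, nrow(a), ncol(a))

  th <- tryCatch(
    costes_thresholds(a, b, mask,
                      regression = config$coloc_regression,
                      max_candidates = config$coloc_max_candidates),
    error = function(e) NULL)
  otsu_fallback <- is.null(th)
  if (otsu_fallback) {
    # anti-correlated channels: the Costes regression is undefined, so fall
    # back to each channel's own Otsu threshold (flagged in the report)
    th <- list(t_a = otsu_threshold(a[mask], config$otsu_bins),
               t_b = otsu_threshold(b[mask], config$otsu_bins),
               slope = NA_real_, intercept = NA_real_,
               degenerate = FALSE, r_below = NA_real_)
  }
  r_all <- pearson(a, b, mask)
  above <- mask & a > th$t_a & b > th$t_b
  r_above <- if (sum(above) >= 2L) pearson(a, b, above)
             else structure(NA_real_, reason = "fewer than 2 above-threshold pixels")
  mm <- manders(a, b, th$t_a, th$t_b, mask)

  structure(list(
    pearson_r = r_all,
    pearson_r_above = r_above,
    costes_threshold_a = th$t_a,
    costes_threshold_b = th$t_b,
    regression_slope = th$slope,
    regression_intercept = th$intercept,
    manders_m1 = mm$m1,
    manders_m2 = mm$m2,
    n_pixels_analysed = sum(mask),
    degenerate_thresholds = th$degenerate,
    r_below_threshold = th$r_below,
    flags = c(if (th$degenerate) "costes_degenerate",
              if (otsu_fallback) "costes_failed_otsu_fallback",
              "manders_thresholds_assumed_costes"),
    params = list(chan_a = if (is.character(chan_a)) chan_a
                           else img2$channel_names[chan_a],
                  chan_b = if (is.character(chan_b)) chan_b
                           else img2$channel_names[chan_b],
                  mask = config$coloc_mask,
                  regression = config$coloc_regression,
                  crop_padding = config$crop_padding,
                  pixel_size = px)),
    class = "coloc_report")
}

#' @export
print.coloc_report <- function(x, ...) {
  cat(sprintf("<coloc_report> %s vs %s over %d px\n",
              x$params$chan_a, x$params$chan_b, x$n_pixels_analysed))
  cat(sprintf("  Pearson r: %.3f (above-threshold: %s)\n", x$pearson_r,
              ifelse(is.na(x$pearson_r_above), "NA",
                     sprintf("%.3f", x$pearson_r_above))))
  cat(sprintf("  Costes thresholds: t_a = %.2f, t_b = %.2f%s\n",
              x$costes_threshold_a, x$costes_threshold_b,
              ifelse(x$degenerate_thresholds, " [degenerate]", "")))
  cat(sprintf("  Manders: M1 = %s, M2 = %s\n",
              ifelse(is.na(x$manders_m1), "NA", sprintf("%.3f", x$manders_m1)),
              ifelse(is.na(x$manders_m2), "NA", sprintf("%.3f", x$manders_m2))))
  invisible(x)
}
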