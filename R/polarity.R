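#' Cell geometry: centre and radius
#'
#' @param center cell centre `(x, y)`, pixels
#' @param radius cell radius, um (> 0)
#' @param source `"nucleus_auto"` (estimated from the nucleus channel) or
#'   `"manual_circle"` (user-supplied)
#' @return an object of class `cell_geometry`
#' @export
cell_geometry <- function(center, radius,
                          source = c("manual_circle", "nucleus_auto")) {
  source <- match.arg(source)
  stopifnot(is.numeric(center), length(center) == 2L, all(is.finite(center)),
            is.numeric(radius), length(radius) == 1L, radius > 0)
  structure(list(center = as.numeric(center), radius = radius,
                 source = source),
            class = "cell_geometry")
}

#' @export
print.cell_geometry <- function(x, ...) {
  cat(sprintf("<cell_geometry> centre (%.2f, %.2f) px, radius %.2f um [%s]\n",
              x$center[1L], x$center[2L], x$radius, x$source))
  invisible(x)
}

#' Logical mask of the cell disk
#'
#' @param geometry a [cell_geometry()]
#' @param dim image dimensions `c(rows, cols)`
#' @param pixel_size um per pixel
#' @return logical matrix, `TRUE` inside the cell circle
#' @export
cell_mask <- function(geometry, dim, pixel_size) {
  stopifnot(inherits(geometry, "cell_geometry"))
  r_px <- geometry$radius / pixel_size
  outer((seq_len(dim[1L]) - geometry$center[2L])^2,
        (seq_len(dim[2L]) - geometry$center[1L])^2, `+`) <= r_px^2
}

#' Estimate the cell centre and radius
#'
#' The reference procedure overlays the nucleus image with a circular mask
#' by hand; this function automates it (Otsu threshold on the nucleus
#' channel, unweighted centroid of the mask, radius of the equal-area
#' circle) for batch work, and echoes a user-supplied circle when given.
#'
#' @param nucleus_channel numeric matrix of the nucleus channel (auto mode);
#'   ignored when `manual` is supplied
#' @param pixel_size um per pixel
#' @param manual optional manual circle `c(x, y, radius_um)`
#' @return a [cell_geometry()]
#' @export
estimate_cell_center <- function(nucleus_channel = NULL, pixel_size,
                                 manual = NULL) {
  if (!is.null(manual)) {
    stopifnot(is.numeric(manual), length(manual) == 3L)
    return(cell_geometry(manual[1:2], manual[3L], source = "manual_circle"))
  }
  stopifnot(is.matrix(nucleus_channel), is.numeric(pixel_size),
            pixel_size > 0)
  t <- tryCatch(otsu_threshold(nucleus_channel), error = function(e)
    stop("nucleus channel is constant; supply a manual circle"))
  mask <- nucleus_channel > t
  n <- sum(mask)
  if (n == 0L)
    stop("empty nucleus mask after thresholding; supply a manual circle")
  idx <- which(mask, arr.ind = TRUE)
  center <- c(mean(idx[, 2L]), mean(idx[, 1L]))  # (x, y)
  radius <- sqrt(n / pi) * pixel_size
  cell_geometry(center, radius, source = "nucleus_auto")
}

#' Intensity-weighted centroid of a channel
#'
#' A local background estimate over a disk of `background_radius` (default
#' 2.6 um) is subtracted first; the centroid is then the mean pixel
#' position weighted by the subtracted intensity, over the masked pixels
#' when a mask is given.
#'
#' By default the background is the local median (`method = "median"`) and
#' the subtracted weights are left signed (`clip_weights = FALSE`): under
#' symmetric noise the residual background weight then cancels instead of
#' accumulating a positive, centre-pulling bias, which matters for the
#' asymmetry statistic. `method = "opening"` with `clip_weights = TRUE`
#' reproduces the plain rolling-ball-style subtraction of
#' [subtract_local_background()].
#'
#' @param img numeric matrix
#' @param pixel_size um per pixel
#' @param background_radius background-estimation disk radius, um;
#'   `NULL` skips the subtraction
#' @param mask optional logical matrix restricting the computation
#' @param method background estimator, `"median"` (default) or `"opening"`
#' @param clip_weights clip negative weights at zero (default `FALSE`)
#' @return centroid `(x, y)` in pixels
#' @export
intensity_centroid <- function(img, pixel_size, background_radius = 2.6,
                               mask = NULL,
                               method = c("median", "opening"),
                               clip_weights = FALSE) {
  stopifnot(is.matrix(img))
  method <- match.arg(method)
  raw_total <- if (is.null(mask)) sum(img) else sum(img[mask])
  w <- if (is.null(background_radius)) img
       else img - local_background(img, background_radius, pixel_size,
                                   method = method)
  if (clip_weights) w <- pmax(w, 0)
  if (!is.null(mask)) {
    stopifnot(is.logical(mask), identical(dim(mask), dim(img)))
    w <- w * mask
  }
  total <- sum(w)
  if (total <= 0) {
    if (raw_total <= 0)
      stop("empty channel: no intensity to locate")
    stop("all intensity removed as background: centroid undefined")
  }
  xs <- matrix(seq_len(ncol(img)), nrow(img), ncol(img), byrow = TRUE)
  ys <- matrix(seq_len(nrow(img)), nrow(img), ncol(img))
  c(sum(xs * w) / total, sum(ys * w) / total)
}

#' Asymmetry: centroid displacement from the cell centre
#'
#' Euclidean distance between the intensity-weighted centroid of the
#' clustered channel and the cell centre, in micrometres. Optionally
#' normalised by the cell radius (off by default — the raw distance is the
#' reported statistic).
#'
#' @param centroid channel centroid `(x, y)`, pixels
#' @param geometry a [cell_geometry()] in the same coordinate frame
#' @param pixel_size um per pixel
#' @param normalise divide by the cell radius (default `FALSE`)
#' @return asymmetry in um (or radius fraction when normalised)
#' @export
asymmetry <- function(centroid, geometry, pixel_size, normalise = FALSE) {
  stopifnot(is.numeric(centroid), length(centroid) == 2L,
            inherits(geometry, "cell_geometry"), pixel_size > 0)
  d <- sqrt(sum((centroid - geometry$center)^2)) * pixel_size
  if (normalise) d / geometry$radius else d
}

.weighted_sd <- function(pos, w) {
  mu <- sum(pos * w) / sum(w)
  sqrt(sum(w * (pos - mu)^2) / sum(w))
}

#' Cluster half-width
#'
#' Over the labelled cluster pixels only, the intensity-weighted standard
#' deviation of the x positions and of the y positions about the
#' intensity-weighted mean, averaged, and converted to micrometres: a
#' compactness measure of the clustered compartment. Weighted population
#' SDs are used (two equal pixels 10 px apart have SD 5 px). Label identity
#' is ignored — all cluster pixels are pooled — so renumbering or splitting
#' labels cannot change the value.
#'
#' @param labels a [label_clusters()] result
#' @param img numeric matrix of intensities (same shape)
#' @param pixel_size um per pixel
#' @return half-width in um, or `NA` (with a `reason` attribute) when there
#'   are no clusters or no intensity on them
#' @export
cluster_half_width <- function(labels, img, pixel_size) {
  stopifnot(inherits(labels, "label_map"), is.matrix(img),
            identical(dim(labels$labels), dim(img)), pixel_size > 0)
  if (labels$n_clusters == 0L)
    return(structure(NA_real_, reason = "no clusters"))
  idx <- which(labels$labels > 0L, arr.ind = TRUE)
  w <- img[idx]
  if (sum(w) <= 0)
    return(structure(NA_real_, reason = "zero cluster intensity"))
  (.weighted_sd(idx[, 2L], w) + .weighted_sd(idx[, 1L], w)) / 2 * pixel_size
}

#' Per-spot intensity and area statistics
#'
#' The mean over clusters of (a) each cluster's mean pixel intensity and
#' (b) each cluster's area in um^2 — the per-cell spot features of
#' high-content imaging readouts.
#'
#' @param labels a [label_clusters()] result
#' @param img numeric matrix of intensities (same shape)
#' @param pixel_size um per pixel
#' @return list with `mean_spot_intensity` and `mean_spot_area_um2`
#'   (both `NA` with a `reason` attribute when there are no clusters)
#' @export
spot_stats <- function(labels, img, pixel_size) {
  stopifnot(inherits(labels, "label_map"), is.matrix(img),
            identical(dim(labels$labels), dim(img)), pixel_size > 0)
  if (labels$n_clusters == 0L) {
    na <- structure(NA_real_, reason = "no clusters")
    return(list(mean_spot_intensity = na, mean_spot_area_um2 = na))
  }
  lab <- labels$labels
  pos <- lab > 0L
  sums <- as.numeric(tapply(img[pos], lab[pos], sum))
  areas <- labels$areas
  list(mean_spot_intensity = mean(sums / areas),
       mean_spot_area_um2 = mean(areas) * pixel_size^2)
}

#' Per-cell polarity metrics for one channel
#'
#' Runs the full measurement chain on one compartment channel of a
#' single-cell crop:
#' max projection -> difference-of-Gaussians bandpass (`config$band`) ->
#' Otsu threshold -> connected-component labeling (min area
#' `config$min_cluster_area`) for the cluster count, half-width and spot
#' features; and, separately, local background subtraction
#' (`config$background_radius`, default 2.6 um) -> intensity-weighted
#' centroid -> asymmetry. Area coverage is the in-cell fraction of raw
#' pixels above their own Otsu threshold. All parameters used are echoed
#' in the result.
#'
#' @param image a [multichannel_image()] (projected internally if a stack)
#' @param channel channel name or index to quantify
#' @param geometry a [cell_geometry()] for the cell
#' @param config a [run_config()]; defaults carry the standard constants
#' @return an object of class `polarity_metrics`
#' @export
compute_polarity_metrics <- function(image, channel, geometry,
                                     config = run_config()) {
  stopifnot(inherits(image, "multichannel_image"),
            inherits(geometry, "cell_geometry"),
            inherits(config, "run_config"))
  px <- image$pixel_size
  geometry <- effective_geometry(geometry, config)
  img2 <- if (n_slices(image) > 1L) max_project(image) else image
  ch <- tryCatch(get_channel(img2, channel),
                 error = function(e) stop("stage get_channel: ",
                                          conditionMessage(e)))
  mask <- if (isTRUE(config$use_cell_mask))
    cell_mask(geometry, dim(ch), px) else NULL

  # segmentation branch: filter -> Otsu -> label
  bp <- tryCatch(
    bandpass(ch, config$band, px, clip = TRUE,
             sigma_rule = config$sigma_rule),
    error = function(e) stop("stage bandpass: ", conditionMessage(e)))
  seg_input <- if (isTRUE(config$background_before_segmentation))
    subtract_local_background(bp, config$background_radius, px) else bp
  t_seg <- tryCatch(otsu_threshold(seg_input, config$otsu_bins),
                    error = function(e) stop("stage otsu: ",
                                             conditionMessage(e)))
  seg_mask <- seg_input > t_seg
  if (!is.null(mask)) seg_mask <- seg_mask & mask
  labels <- label_clusters(seg_mask, config$min_cluster_area,
                           config$connectivity)
  hw_img <- if (identical(config$half_width_on, "bandpassed")) bp else ch
  hw <- cluster_half_width(labels, hw_img, px)
  ss <- spot_stats(labels, ch, px)

  # centroid branch: background subtraction -> weighted centroid -> asymmetry
  centroid <- tryCatch(
    intensity_centroid(ch, px, config$background_radius, mask = mask,
                       method = config$centroid_background,
                       clip_weights = isTRUE(config$centroid_clip_weights)),
    error = function(e) stop("stage intensity_centroid: ",
                             conditionMessage(e)))
  asym <- asymmetry(centroid, geometry, px,
                    normalise = isTRUE(config$normalise_asymmetry))

  cov <- tryCatch(
    area_coverage(ch, otsu_threshold(ch, config$otsu_bins), mask = mask),
    error = function(e) structure(NA_real_, reason = conditionMessage(e)))

  structure(list(
    channel = if (is.character(channel)) channel
              else img2$channel_names[channel],
    cluster_count = labels$n_clusters,
    asymmetry_um = asym,
    half_width_um = hw,
    area_coverage = cov,
    mean_spot_intensity = ss$mean_spot_intensity,
    mean_spot_area_um2 = ss$mean_spot_area_um2,
    centroid_px = centroid,
    segmentation_threshold = t_seg,
    geometry = geometry,
    params = list(
      pixel_size = px, band = unclass(config$band),
      background_radius = config$background_radius,
      centroid_background = config$centroid_background,
      centroid_clip_weights = isTRUE(config$centroid_clip_weights),
      otsu_bins = config$otsu_bins,
      min_cluster_area = config$min_cluster_area,
      connectivity = config$connectivity,
      sigma_rule = config$sigma_rule,
      half_width_on = config$half_width_on,
      background_before_segmentation =
        isTRUE(config$background_before_segmentation),
      use_cell_mask = isTRUE(config$use_cell_mask))),
    class = "polarity_metrics")
}

#' @export
print.polarity_metrics <- function(x, ...) {
  cat(sprintf("<polarity_metrics> channel '%s'\n", x$channel))
  cat(sprintf("  clusters: %d   asymmetry: %.3f um   half-width: %s um\n",
              x$cluster_count, x$asymmetry_um,
              ifelse(is.na(x$half_width_um), "NA",
                     sprintf("%.3f", x$half_width_um))))
  cat(sprintf("  area coverage: %s   mean spot intensity: %s   mean spot area: %s um^2\n",
              ifelse(is.na(x$area_coverage), "NA",
                     sprintf("%.3f", x$area_coverage)),
              ifelse(is.na(x$mean_spot_intensity), "NA",
                     sprintf("%.1f", x$mean_spot_intensity)),
              ifelse(is.na(x$mean_spot_area_um2), "NA",
                     sprintf("%.4f", x$mean_spot_area_um2))))
  invisible(x)
}

#' Cell-sized geometry from a possibly nucleus-derived one
#'
#' A nucleus-derived circle marks the cell centre but understates the cell
#' extent; `config$cell_mask_scale` (default 1.25, a typical lymphocyte
#' cytoplasmic allowance) inflates the radius of `nucleus_auto` geometries
#' before they are used as cell masks or crop bounds. Manual circles are
#' taken as true cell outlines and returned unchanged.
#'
#' @param geometry a [cell_geometry()]
#' @param config a [run_config()]
#' @return a [cell_geometry()] with the working cell radius
#' @export
effective_geometry <- function(geometry, config) {
  stopifnot(inherits(geometry, "cell_geometry"),
            inherits(config, "run_config"))
  if (identical(geometry$source, "nucleus_auto"))
    geometry$radius <- geometry$radius * config$cell_mask_scale
  geometry
}

#' Classify a cell as polarised
#'
#' Convenience threshold on the asymmetry statistic: `TRUE` iff asymmetry
#' strictly exceeds `asymmetry_threshold`. No default threshold is asserted
#' as biological truth — calibrate it on synthetic or annotated data.
#'
#' @param metrics a [compute_polarity_metrics()] result, or a single
#'   asymmetry value in um
#' @param asymmetry_threshold decision threshold, um
#' @return logical flag
#' @export
classify_polarised <- function(metrics, asymmetry_threshold) {
  stopifnot(is.numeric(asymmetry_threshold),
            length(asymmetry_threshold) == 1L)
  a <- if (inherits(metrics, "polarity_metrics")) metrics$asymmetry_um
       else metrics
  if (!is.numeric(a) || length(a) != 1L || is.na(a))
    stop("asymmetry is undefined; cannot classify")
  a > asymmetry_threshold
}
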