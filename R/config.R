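#' Pipeline configuration
#'
#' Collects every tunable parameter of the analysis chain. Defaults marked
#' "standard constant" are the published analysis constants (bandpass
#' scales 0.13-0.9 um, background-subtraction radius 2.6 um, Otsu
#' segmentation); the rest are artifact choices documented in the methods
#' vignette.
#'
#' @param pixel_size um per pixel (used when an image carries no metadata)
#' @param band a [filter_band()]; default 0.13-0.9 um (standard constant)
#' @param background_radius background disk radius, um; default 2.6
#'   (standard constant)
#' @param centroid_background background estimator for the centroid branch,
#'   `"median"` (default; unbiased under noise) or `"opening"`
#' @param centroid_clip_weights clip negative centroid weights at zero
#'   (default `FALSE`; see [intensity_centroid()])
#' @param otsu_bins histogram bins for Otsu thresholding (default 256)
#' @param min_cluster_area minimum cluster area, px (default 4)
#' @param connectivity component connectivity, 4 or 8 (default 8)
#' @param sigma_rule scale-to-sigma mapping for the bandpass, `"half"` or
#'   `"fwhm"`
#' @param half_width_on compute the half-width on the `"raw"` or
#'   `"bandpassed"` channel
#' @param background_before_segmentation also subtract the local background
#'   before segmentation (default `FALSE`: the subtraction belongs to the
#'   centroid computation)
#' @param normalise_asymmetry report asymmetry as a fraction of the cell
#'   radius (default `FALSE`: raw um)
#' @param use_cell_mask restrict centroid/coverage/segmentation to the cell
#'   circle (default `TRUE`)
#' @param cell_mask_scale radius inflation applied to nucleus-derived
#'   geometries to approximate the cell outline (default 1.25; see
#'   [effective_geometry()])
#' @param channel_roles named list mapping roles `nucleus`,
#'   `compartment_a`, `compartment_b` to channel names
#' @param coloc_mask `"cell_circle"` or `"crop_rectangle"`
#' @param coloc_regression `"tls"` (orthogonal) or `"ols"`
#' @param coloc_max_candidates cap on Costes threshold candidates
#' @param crop_padding crop margin around the cell circle, um
#' @param seed RNG seed for simulation subcommands
#' @param output_dir optional output directory for batch results
#' @return an object of class `run_config`
#' @export
run_config <- function(pixel_size = 0.08,
                       band = filter_band(0.13, 0.9),
                       background_radius = 2.6,
                       centroid_background = "median",
                       centroid_clip_weights = FALSE,
                       otsu_bins = 256L,
                       min_cluster_area = 4L,
                       connectivity = 8L,
                       sigma_rule = "half",
                       half_width_on = "raw",
                       background_before_segmentation = FALSE,
                       normalise_asymmetry = FALSE,
                       use_cell_mask = TRUE,
                       cell_mask_scale = 1.25,
                       channel_roles = list(nucleus = "nucleus",
                                            compartment_a = "puncta",
                                            compartment_b = NULL),
                       coloc_mask = "cell_circle",
                       coloc_regression = "tls",
                       coloc_max_candidates = 512L,
                       crop_padding = 0.2,
                       seed = 1L,
                       output_dir = NULL) {
  stopifnot(is.numeric(pixel_size), pixel_size > 0,
            inherits(band, "filter_band"),
            is.numeric(background_radius), background_radius > 0,
            centroid_background %in% c("median", "opening"),
            is.logical(centroid_clip_weights),
            otsu_bins >= 2L, min_cluster_area >= 1L,
            connectivity %in% c(4L, 8L),
            sigma_rule %in% c("half", "fwhm"),
            half_width_on %in% c("raw", "bandpassed"),
            is.logical(background_before_segmentation),
            is.logical(normalise_asymmetry), is.logical(use_cell_mask),
            is.numeric(cell_mask_scale), cell_mask_scale > 0,
            is.list(channel_roles),
            coloc_mask %in% c("cell_circle", "crop_rectangle"),
            coloc_regression %in% c("tls", "ols"),
            coloc_max_candidates >= 2L,
            is.numeric(crop_padding), crop_padding >= 0,
            is.numeric(seed))
  structure(list(
    schema_version = 1L,
    pixel_size = pixel_size, band = band,
    background_radius = background_radius,
    centroid_background = centroid_background,
    centroid_clip_weights = centroid_clip_weights,
    otsu_bins = as.integer(otsu_bins),
    min_cluster_area = as.integer(min_cluster_area),
    connectivity = as.integer(connectivity),
    sigma_rule = sigma_rule, half_width_on = half_width_on,
    background_before_segmentation = background_before_segmentation,
    normalise_asymmetry = normalise_asymmetry,
    use_cell_mask = use_cell_mask,
    cell_mask_scale = cell_mask_scale,
    channel_roles = channel_roles,
    coloc_mask = coloc_mask, coloc_regression = coloc_regression,
    coloc_max_candidates = as.integer(coloc_max_candidates),
    crop_padding = crop_padding,
    seed = as.integer(seed), output_dir = output_dir),
    class = "run_config")
}

#' @export
print.run_config <- function(x, ...) {
  cat("<run_config> (schema v", x$schema_version, ")\n", sep = "")
  cat(sprintf("  pixel_size: %.4g um/px\n", x$pixel_size))
  cat(sprintf("  band: %.3g - %.3g um (sigma rule: %s)\n",
              x$band$low_scale, x$band$high_scale, x$sigma_rule))
  cat(sprintf("  background radius: %.3g um (centroid estimator: %s%s)\n",
              x$background_radius, x$centroid_background,
              ifelse(x$centroid_clip_weights, ", clipped", "")))
  cat(sprintf("  otsu bins: %d   min cluster area: %d px   connectivity: %d\n",
              x$otsu_bins, x$min_cluster_area, x$connectivity))
  cat(sprintf("  coloc: mask=%s regression=%s candidates<=%d padding=%.3g um\n",
              x$coloc_mask, x$coloc_regression, x$coloc_max_candidates,
              x$crop_padding))
  roles <- vapply(names(x$channel_roles), function(r)
    sprintf("%s=%s", r, ifelse(is.null(x$channel_roles[[r]]), "<none>",
                               x$channel_roles[[r]])), "")
  cat("  channel roles:", paste(roles, collapse = " "), "\n")
  cat(sprintf("  seed: %d\n", x$seed))
  invisible(x)
}

#' Read a pipeline configuration from YAML
#'
#' Unknown keys are an error (they usually mean a typo); missing keys take
#' their defaults. The parsed file must carry `schema_version: 1`.
#'
#' @param path YAML file path
#' @return a [run_config()]
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop(sprintf("config file '%s' not found", path))
  raw <- yaml::read_yaml(path)
  if (is.null(raw$schema_version) || raw$schema_version != 1L)
    stop("config file must declare schema_version: 1")
  raw$schema_version <- NULL
  if (!is.null(raw$band))
    raw$band <- filter_band(raw$band$low_scale, raw$band$high_scale)
  known <- names(formals(run_config))
  unknown <- setdiff(names(raw), known)
  if (length(unknown) > 0L)
    stop("unknown config keys: ", paste(unknown, collapse = ", "))
  do.call(run_config, raw)
}

#' Write a pipeline configuration as YAML
#'
#' @param config a [run_config()]
#' @param path output file path
#' @return `path`, invisibly
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  out <- unclass(config)
  out$band <- list(low_scale = config$band$low_scale,
                   high_scale = config$band$high_scale)
  out <- out[!vapply(out, is.null, TRUE)]
  yaml::write_yaml(out, path)
  invisible(path)
}
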