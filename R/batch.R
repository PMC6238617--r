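.pkg_version <- function() {
  as.character(utils::packageVersion("polcoloc"))
}

.resolve_geometry <- function(image, config) {
  nuc <- config$channel_roles$nucleus
  if (is.null(nuc) || !nuc %in% image$channel_names)
    stop("no nucleus channel configured/present; cannot estimate geometry")
  img2 <- if (n_slices(image) > 1L) max_project(image) else image
  estimate_cell_center(get_channel(img2, nuc), image$pixel_size)
}

#' Run the full analysis over a batch of cells
#'
#' Accepts TIFF file paths or a [simulate_population()] result. Each cell
#' yields one polarity row per configured compartment channel and, when
#' both `compartment_a` and `compartment_b` resolve, one colocalisation
#' row. Per-cell failures are recorded and never abort the batch; the
#' function only errors when every cell failed. With
#' `config$output_dir` set, `polarity.csv`, `colocalisation.csv` and
#' `failures.csv` are written with a parameter-echo comment header
#' (deterministic: no timestamps).
#'
#' @param inputs character vector of TIFF paths, or a `cell_population`
#' @param config a [run_config()]
#' @return list with data frames `polarity`, `colocalisation`, `failures`
#' @export
run_batch <- function(inputs, config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  if (inherits(inputs, "cell_population")) {
    ids <- inputs$ground_truth$cell_id
    loader <- function(i) inputs$cells[[i]]$image
    n <- length(inputs$cells)
  } else if (is.character(inputs) && length(inputs) >= 1L) {
    ids <- basename(inputs)
    loader <- function(i) read_image(inputs[i],
                                     pixel_size = config$pixel_size)
    n <- length(inputs)
  } else {
    stop("inputs must be >= 1 TIFF paths or a cell_population")
  }

  roles <- config$channel_roles
  pol_rows <- list(); col_rows <- list(); fail_rows <- list()
  for (i in seq_len(n)) {
    res <- tryCatch({
      image <- loader(i)
      geom <- .resolve_geometry(image, config)
      compartments <- Filter(
        function(ch) !is.null(ch) && ch %in% image$channel_names,
        roles[c("compartment_a", "compartment_b")])
      if (length(compartments) == 0L)
        stop("no configured compartment channel present in image")
      prow <- lapply(compartments, function(ch) {
        m <- compute_polarity_metrics(image, ch, geom, config)
        data.frame(
          cell_id = ids[i], channel = ch,
          cluster_count = m$cluster_count,
          asymmetry_um = m$asymmetry_um,
          half_width_um = as.numeric(m$half_width_um),
          area_coverage = as.numeric(m$area_coverage),
          mean_spot_intensity = as.numeric(m$mean_spot_intensity),
          mean_spot_area_um2 = as.numeric(m$mean_spot_area_um2),
          geometry_source = geom$source,
          cell_radius_um = geom$radius,
          stringsAsFactors = FALSE)
      })
      crow <- NULL
      if (length(compartments) == 2L) {
        # a coloc failure must not discard the cell's polarity rows
        r <- tryCatch(
          colocalise_cell(image, geom, compartments[[1L]],
                          compartments[[2L]], config),
          error = function(e) e)
        crow <- if (inherits(r, "error")) data.frame(
          cell_id = ids[i],
          chan_a = compartments[[1L]], chan_b = compartments[[2L]],
          pearson_r_all = NA_real_,
          pearson_r_above_threshold = NA_real_,
          t_a = NA_real_, t_b = NA_real_,
          m1 = NA_real_, m2 = NA_real_, n_pixels = NA_integer_,
          flags = paste0("coloc_error:", conditionMessage(r)),
          stringsAsFactors = FALSE)
        else data.frame(
          cell_id = ids[i],
          chan_a = r$params$chan_a, chan_b = r$params$chan_b,
          pearson_r_all = as.numeric(r$pearson_r),
          pearson_r_above_threshold = as.numeric(r$pearson_r_above),
          t_a = r$costes_threshold_a, t_b = r$costes_threshold_b,
          m1 = as.numeric(r$manders_m1), m2 = as.numeric(r$manders_m2),
          n_pixels = r$n_pixels_analysed,
          flags = paste(r$flags, collapse = ";"),
          stringsAsFactors = FALSE)
      }
      list(polarity = do.call(rbind, unname(prow)), coloc = crow)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      fail_rows[[length(fail_rows) + 1L]] <-
        data.frame(cell_id = ids[i], error = conditionMessage(res),
                   stringsAsFactors = FALSE)
    } else {
      pol_rows[[length(pol_rows) + 1L]] <- res$polarity
      if (!is.null(res$coloc))
        col_rows[[length(col_rows) + 1L]] <- res$coloc
    }
  }
  if (length(pol_rows) == 0L)
    stop(sprintf("all %d cell(s) failed; first error: %s", n,
                 fail_rows[[1L]]$error))

  empty <- function(cols) as.data.frame(
    stats::setNames(rep(list(character(0)), length(cols)), cols))
  out <- list(
    polarity = do.call(rbind, pol_rows),
    colocalisation = if (length(col_rows) > 0L) do.call(rbind, col_rows)
                     else NULL,
    failures = if (length(fail_rows) > 0L) do.call(rbind, fail_rows)
               else empty(c("cell_id", "error")))
  rownames(out$polarity) <- NULL
  if (!is.null(out$colocalisation)) rownames(out$colocalisation) <- NULL

  if (!is.null(config$output_dir)) {
    dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
    write_results_csv(out$polarity,
                      file.path(config$output_dir, "polarity.csv"), config)
    if (!is.null(out$colocalisation))
      write_results_csv(out$colocalisation,
                        file.path(config$output_dir, "colocalisation.csv"),
                        config)
    write_results_csv(out$failures,
                      file.path(config$output_dir, "failures.csv"), config)
  }
  out
}

#' Write a results table with a provenance header
#'
#' Prepends `#`-prefixed comment lines echoing the tool version and every
#' pipeline parameter (no timestamps, so identical runs give byte-identical
#' files), then the CSV body. Read back with
#' `read.csv(path, comment.char = "#")`.
#'
#' @param df data frame to write
#' @param path output path
#' @param config the [run_config()] used to produce `df`
#' @return `path`, invisibly
#' @export
write_results_csv <- function(df, path, config) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# polcoloc %s", .pkg_version()), con)
  writeLines(sprintf(
    "# pixel_size=%.6g band=%.6g-%.6g bg_radius=%.6g otsu_bins=%d min_area=%d connectivity=%d",
    config$pixel_size, config$band$low_scale, config$band$high_scale,
    config$background_radius, config$otsu_bins, config$min_cluster_area,
    config$connectivity), con)
  writeLines(sprintf(
    "# sigma_rule=%s half_width_on=%s coloc_mask=%s regression=%s seed=%d",
    config$sigma_rule, config$half_width_on, config$coloc_mask,
    config$coloc_regression, config$seed), con)
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}
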