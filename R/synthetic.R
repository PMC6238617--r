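# Synthetic single-cell image generator.
#
# Emulates confocal crops of single lymphocytes: a roughly circular cell
# (~3-4 um radius) with a nucleus channel and one or two punctate
# compartment channels whose diffraction-limited spots are placed either
# uniformly ("cage-like") or displaced towards one pole ("collapsed /
# polarised"). Every planted quantity is recorded as ground truth so that
# the measurement pipeline can be benchmarked against known answers.

.NUCLEUS_AMPLITUDE <- 100

.with_seed <- function(seed, expr) {
  if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

#' Scene geometry of a synthetic cell
#'
#' @param image_shape image size in pixels, `c(rows, cols)`
#' @param pixel_size um per pixel; the 0.08 um default corresponds to
#'   Nyquist-ish sampling on a 63x/1.4 NA confocal and is a stand-in, not a
#'   measured acquisition parameter
#' @param cell_center cell centre `(x, y)` in pixels; default image centre
#' @param cell_radius cell radius, um
#' @param nucleus_radius nucleus radius, um (< cell_radius); lymphocytes
#'   have a high nuclear-to-cytoplasmic ratio, hence the 2.8 um default
#'   inside a 3.5 um cell
#' @param background_level additive background intensity
#' @return an object of class `scene_spec`
#' @export
scene_spec <- function(image_shape = c(128L, 128L), pixel_size = 0.08,
                       cell_center = NULL, cell_radius = 3.5,
                       nucleus_radius = 2.8, background_level = 20) {
  stopifnot(length(image_shape) == 2L, all(image_shape >= 8L),
            is.numeric(pixel_size), pixel_size > 0,
            is.numeric(cell_radius), cell_radius > 0,
            is.numeric(nucleus_radius),
            is.numeric(background_level), background_level >= 0)
  if (nucleus_radius <= 0 || nucleus_radius >= cell_radius)
    stop("need 0 < nucleus_radius < cell_radius")
  if (is.null(cell_center))
    cell_center <- c((image_shape[2L] + 1) / 2, (image_shape[1L] + 1) / 2)
  r_px <- cell_radius / pixel_size
  if (cell_center[1L] - r_px < 1 || cell_center[1L] + r_px > image_shape[2L] ||
      cell_center[2L] - r_px < 1 || cell_center[2L] + r_px > image_shape[1L])
    stop("cell circle does not fit inside the image bounds")
  structure(list(image_shape = as.integer(image_shape),
                 pixel_size = pixel_size, cell_center = cell_center,
                 cell_radius = cell_radius, nucleus_radius = nucleus_radius,
                 background_level = background_level),
            class = "scene_spec")
}

#' Specification of one punctate compartment channel
#'
#' Spots are drawn from an isotropic Gaussian whose centre sits
#' `polarisation_offset` um from the cell centre along
#' `polarisation_angle`; `polarisation_offset = 0` gives the uniform
#' cage-like phenotype, larger offsets the collapsed/polarised one.
#' Placement is rejection-sampled to stay inside the cell disk (and, when
#' `min_separation > 0`, pairwise separated — used to plant well-separated
#' countable puncta).
#'
#' @param n_puncta number of spots (>= 0)
#' @param puncta_sigma PSF-like Gaussian width of one spot, um
#' @param amplitude peak intensity of one spot
#' @param polarisation_offset distance of the spot-distribution centre from
#'   the cell centre, um; must satisfy
#'   `polarisation_offset + placement_spread <= cell_radius`
#' @param polarisation_angle direction of the offset, radians from +x
#'   towards +y
#' @param placement_spread SD of spot positions about the distribution
#'   centre, um
#' @param min_separation minimum pairwise spot distance, um (default 0)
#' @param name channel name
#' @return an object of class `puncta_channel_spec`
#' @export
puncta_channel_spec <- function(n_puncta = 40L, puncta_sigma = 0.12,
                                amplitude = 150, polarisation_offset = 0,
                                polarisation_angle = 0,
                                placement_spread = 1.5,
                                min_separation = 0, name = "puncta") {
  stopifnot(is.numeric(n_puncta), n_puncta >= 0,
            is.numeric(puncta_sigma), puncta_sigma > 0,
            is.numeric(amplitude), amplitude > 0,
            is.numeric(polarisation_offset), polarisation_offset >= 0,
            is.numeric(polarisation_angle),
            is.numeric(placement_spread), placement_spread > 0,
            is.numeric(min_separation), min_separation >= 0,
            is.character(name), nzchar(name))
  structure(list(n_puncta = as.integer(n_puncta),
                 puncta_sigma = puncta_sigma, amplitude = amplitude,
                 polarisation_offset = polarisation_offset,
                 polarisation_angle = polarisation_angle,
                 placement_spread = placement_spread,
                 min_separation = min_separation, name = name),
            class = "puncta_channel_spec")
}

#' Acquisition noise model
#'
#' Shot noise (Poisson resampling of each pixel's expected intensity) is
#' applied after PSF rendering; Gaussian read noise of SD `gaussian_sd` is
#' added last; the result is clipped at zero.
#'
#' @param gaussian_sd read-noise SD, intensity units (>= 0)
#' @param shot_noise logical, apply intensity-dependent Poisson noise
#' @param seed RNG seed; identical specs and seed give identical images
#' @return an object of class `noise_spec`
#' @export
noise_spec <- function(gaussian_sd = 2, shot_noise = TRUE, seed = 1L) {
  stopifnot(is.numeric(gaussian_sd), gaussian_sd >= 0,
            is.logical(shot_noise), is.numeric(seed))
  structure(list(gaussian_sd = gaussian_sd, shot_noise = shot_noise,
                 seed = as.integer(seed)),
            class = "noise_spec")
}

.place_puncta <- function(spec, scene, n_needed, existing = NULL) {
  px <- scene$pixel_size
  cx <- scene$cell_center[1L]; cy <- scene$cell_center[2L]
  centre_x <- cx + spec$polarisation_offset / px * cos(spec$polarisation_angle)
  centre_y <- cy + spec$polarisation_offset / px * sin(spec$polarisation_angle)
  spread_px <- spec$placement_spread / px
  r_px <- scene$cell_radius / px
  sep_px <- spec$min_separation / px
  pts <- if (is.null(existing)) matrix(numeric(0), 0L, 2L) else existing
  n_have0 <- nrow(pts)
  attempts <- 0L
  max_attempts <- 500L * n_needed + 500L
  while (nrow(pts) < n_have0 + n_needed) {
    if (attempts >= max_attempts)
      stop(sprintf(paste0(
        "cannot place %d puncta inside the cell disk for channel '%s' ",
        "(offset %.2f um, spread %.2f um, min_separation %.2f um)"),
        n_needed, spec$name, spec$polarisation_offset,
        spec$placement_spread, spec$min_separation))
    attempts <- attempts + 1L
    cand <- c(stats::rnorm(1L, centre_x, spread_px),
              stats::rnorm(1L, centre_y, spread_px))
    if ((cand[1L] - cx)^2 + (cand[2L] - cy)^2 > r_px^2) next
    if (sep_px > 0 && nrow(pts) > 0L &&
        min((pts[, 1L] - cand[1L])^2 + (pts[, 2L] - cand[2L])^2) < sep_px^2)
      next
    pts <- rbind(pts, cand)
  }
  unname(pts)
}

.render_spots <- function(shape, spots, sigma_px, amplitude) {
  out <- matrix(0, shape[1L], shape[2L])
  if (nrow(spots) == 0L) return(out)
  ys <- seq_len(shape[1L]); xs <- seq_len(shape[2L])
  for (s in seq_len(nrow(spots))) {
    gx <- exp(-(xs - spots[s, 1L])^2 / (2 * sigma_px^2))
    gy <- exp(-(ys - spots[s, 2L])^2 / (2 * sigma_px^2))
    out <- out + amplitude * outer(gy, gx)
  }
  out
}

.apply_noise <- function(m, noise) {
  if (noise$shot_noise) m <- matrix(stats::rpois(length(m), m), nrow(m))
  if (noise$gaussian_sd > 0)
    m <- m + stats::rnorm(length(m), 0, noise$gaussian_sd)
  pmax(m, 0)
}

#' Simulate one synthetic cell with known ground truth
#'
#' Channel 1 of the output is always the nucleus (a PSF-blurred filled disk
#' of `nucleus_radius` at the cell centre); the supplied puncta channels
#' follow. When two or more puncta channels are given, `overlap_fraction`
#' of the second channel's spot centres are reused from the first channel
#' (the colocalisation knob); the realised fraction is recorded as
#' `true_overlap_fraction`.
#'
#' @param scene a [scene_spec()]
#' @param channels list of [puncta_channel_spec()]s
#' @param noise a [noise_spec()]
#' @param overlap_fraction fraction in `[0, 1]` of channel 2's spots shared
#'   with channel 1 (ignored with a single puncta channel)
#' @param keep_noiseless keep the noiseless channel renders in the result
#'   (used by tests and oracles; default `TRUE`)
#' @return an object of class `synthetic_cell`: list with `image` (a
#'   [multichannel_image()]), `truth` (planted values), `spots` (list of
#'   spot-centre matrices, columns x and y, pixels) and optionally
#'   `noiseless`
#' @export
simulate_cell <- function(scene, channels, noise = noise_spec(),
                          overlap_fraction = 0, keep_noiseless = TRUE) {
  stopifnot(inherits(scene, "scene_spec"), is.list(channels),
            length(channels) >= 1L, inherits(noise, "noise_spec"),
            overlap_fraction >= 0, overlap_fraction <= 1)
  for (ch in channels) {
    stopifnot(inherits(ch, "puncta_channel_spec"))
    if (ch$polarisation_offset + ch$placement_spread > scene$cell_radius)
      stop(sprintf(paste0(
        "channel '%s': polarisation_offset + placement_spread ",
        "(%.2f + %.2f um) exceeds the cell radius (%.2f um)"),
        ch$name, ch$polarisation_offset, ch$placement_spread,
        scene$cell_radius))
  }
  nm <- vapply(channels, `[[`, "", "name")
  if (anyDuplicated(c("nucleus", nm)))
    stop("channel names must be unique and distinct from 'nucleus'")

  px <- scene$pixel_size
  shape <- scene$image_shape
  .with_seed(noise$seed, {
    # spot placement
    spots <- vector("list", length(channels))
    names(spots) <- nm
    for (i in seq_along(channels)) {
      ch <- channels[[i]]
      if (i == 2L && overlap_fraction > 0 && ch$n_puncta > 0L) {
        n_shared <- min(round(overlap_fraction * ch$n_puncta),
                        nrow(spots[[1L]]))
        shared <- spots[[1L]][seq_len(n_shared), , drop = FALSE]
        fresh_n <- ch$n_puncta - n_shared
        spots[[i]] <- if (fresh_n > 0L)
          .place_puncta(ch, scene, fresh_n, existing = shared)
        else shared
      } else {
        spots[[i]] <- if (ch$n_puncta > 0L)
          .place_puncta(ch, scene, ch$n_puncta)
        else matrix(numeric(0), 0L, 2L)
      }
    }

    # noiseless renders
    ys <- seq_len(shape[1L]); xs <- seq_len(shape[2L])
    dist2 <- outer((ys - scene$cell_center[2L])^2,
                   (xs - scene$cell_center[1L])^2, `+`)
    nucleus <- matrix(0, shape[1L], shape[2L])
    nucleus[dist2 <= (scene$nucleus_radius / px)^2] <- .NUCLEUS_AMPLITUDE
    nucleus <- gaussian_blur(nucleus, 0.1 / px) + scene$background_level
    noiseless <- c(list(nucleus = nucleus),
                   lapply(seq_along(channels), function(i)
                     .render_spots(shape, spots[[i]],
                                   channels[[i]]$puncta_sigma / px,
                                   channels[[i]]$amplitude) +
                       scene$background_level))
    names(noiseless) <- c("nucleus", nm)

    noisy <- lapply(noiseless, .apply_noise, noise = noise)

    image <- multichannel_image(noisy, px, names(noiseless))
    first <- channels[[1L]]
    truth <- list(
      true_center = scene$cell_center,
      true_centroid_per_channel = lapply(spots, function(s)
        if (nrow(s) > 0L) colMeans(s) else c(NA_real_, NA_real_)),
      true_asymmetry = first$polarisation_offset,
      true_cluster_count = first$n_puncta,
      true_overlap_fraction = if (length(channels) >= 2L &&
                                  channels[[2L]]$n_puncta > 0L)
        min(round(overlap_fraction * channels[[2L]]$n_puncta),
            nrow(spots[[1L]])) / channels[[2L]]$n_puncta
      else NA_real_)
    out <- list(image = image, truth = truth, spots = spots,
                scene = scene, channel_specs = channels, noise = noise)
    if (keep_noiseless) out$noiseless <- noiseless
    structure(out, class = "synthetic_cell")
  })
}

#' @export
print.synthetic_cell <- function(x, ...) {
  cat(sprintf(
    "<synthetic_cell> planted asymmetry %.2f um, %d puncta, overlap %s\n",
    x$truth$true_asymmetry, x$truth$true_cluster_count,
    ifelse(is.na(x$truth$true_overlap_fraction), "n/a",
           sprintf("%.2f", x$truth$true_overlap_fraction))))
  print(x$image)
  invisible(x)
}

#' Simulate a population of synthetic cells
#'
#' Per-cell seeds are derived deterministically from `master_seed`, so the
#' same call yields byte-identical images and ground-truth tables.
#' `offsets` and `overlap_fractions`, when given, are recycled across cells
#' and override the first puncta channel's `polarisation_offset` and the
#' channel-pair overlap respectively — the usual way of planting mixed
#' populations.
#'
#' @param n_cells number of cells (>= 1)
#' @param scene a [scene_spec()] shared by all cells
#' @param channels list of [puncta_channel_spec()]s (template for every cell)
#' @param noise a [noise_spec()]; its seed is used as `master_seed` default
#' @param master_seed master RNG seed
#' @param offsets optional vector of polarisation offsets, um, recycled
#' @param overlap_fractions optional vector of overlap fractions, recycled
#' @return an object of class `cell_population`: list of `synthetic_cell`s
#'   plus a `ground_truth` data frame (one row per cell)
#' @export
simulate_population <- function(n_cells, scene = scene_spec(),
                                channels = list(puncta_channel_spec()),
                                noise = noise_spec(),
                                master_seed = noise$seed,
                                offsets = NULL, overlap_fractions = NULL) {
  if (!is.numeric(n_cells) || length(n_cells) != 1L || n_cells < 1)
    stop("n_cells must be >= 1")
  n_cells <- as.integer(n_cells)
  if (!is.null(offsets) && (!is.numeric(offsets) || any(offsets < 0)))
    stop("offsets must be non-negative numbers")
  if (!is.null(overlap_fractions) &&
      (!is.numeric(overlap_fractions) || any(overlap_fractions < 0) ||
       any(overlap_fractions > 1)))
    stop("overlap_fractions must lie in [0, 1]")
  cell_seeds <- .with_seed(master_seed,
                           sample.int(2147483646L, n_cells, replace = FALSE))
  cells <- vector("list", n_cells)
  rows <- vector("list", n_cells)
  for (i in seq_len(n_cells)) {
    ch <- channels
    off <- if (is.null(offsets)) ch[[1L]]$polarisation_offset
           else offsets[(i - 1L) %% length(offsets) + 1L]
    ch[[1L]]$polarisation_offset <- off
    ovl <- if (is.null(overlap_fractions)) 0
           else overlap_fractions[(i - 1L) %% length(overlap_fractions) + 1L]
    ni <- noise; ni$seed <- cell_seeds[i]
    cell <- simulate_cell(scene, ch, ni, overlap_fraction = ovl,
                          keep_noiseless = FALSE)
    cells[[i]] <- cell
    tr <- cell$truth
    rows[[i]] <- data.frame(
      cell_id = sprintf("cell_%04d", i), seed = cell_seeds[i],
      polarisation_offset_um = off,
      polarisation_angle_rad = ch[[1L]]$polarisation_angle,
      n_puncta = ch[[1L]]$n_puncta,
      true_asymmetry_um = tr$true_asymmetry,
      true_cluster_count = tr$true_cluster_count,
      true_centroid_x_px = tr$true_centroid_per_channel[[1L]][1L],
      true_centroid_y_px = tr$true_centroid_per_channel[[1L]][2L],
      true_overlap_fraction = tr$true_overlap_fraction,
      stringsAsFactors = FALSE)
  }
  structure(list(cells = cells, ground_truth = do.call(rbind, rows),
                 scene = scene, master_seed = master_seed),
            class = "cell_population")
}

#' @export
print.cell_population <- function(x, ...) {
  cat(sprintf("<cell_population> %d cell(s), master seed %d\n",
              length(x$cells), x$master_seed))
  invisible(x)
}

#' Write a simulated population to disk
#'
#' One multi-page TIFF per cell plus `ground_truth.csv` (one row per cell).
#'
#' @param population a [simulate_population()] result
#' @param dir output directory (created if missing)
#' @param dtype TIFF sample type, `"float64"` (exact), `"float32"` or
#'   `"uint16"`
#' @return `dir`, invisibly
#' @export
write_population <- function(population, dir, dtype = "float64") {
  stopifnot(inherits(population, "cell_population"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  gt <- population$ground_truth
  gt$file <- paste0(gt$cell_id, ".tif")
  for (i in seq_along(population$cells))
    write_image(population$cells[[i]]$image,
                file.path(dir, gt$file[i]), dtype = dtype)
  utils::write.csv(gt, file.path(dir, "ground_truth.csv"),
                   row.names = FALSE)
  invisible(dir)
}
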