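#' Multi-channel single-cell image
#'
#' The universal input container of the package: a list of per-channel
#' intensity grids sharing one shape, plus the physical pixel size in
#' micrometres per pixel. Each channel is either a 2D `matrix` (rows = y,
#' columns = x) or a 3D `array` with dimensions `(z, y, x)` for a z-stack.
#'
#' Coordinate convention throughout the package: `x` is the column index,
#' `y` the row index, origin at the top-left pixel, pixel centres at integer
#' (1-based) coordinates. Angles are measured from the +x axis towards +y
#' (i.e. clockwise on screen, since y points down).
#'
#' @param channels list of numeric matrices or `(z, y, x)` arrays, all with
#'   identical spatial shape; intensities must be finite and non-negative.
#' @param pixel_size physical pixel size, micrometres per pixel (> 0).
#' @param channel_names character vector naming the channels; defaults to
#'   `names(channels)` or `"ch1"`, `"ch2"`, ...
#' @return An object of class `multichannel_image`.
#' @export
multichannel_image <- function(channels, pixel_size, channel_names = NULL) {
  if (!is.list(channels) || length(channels) == 0L)
    stop("'channels' must be a non-empty list of matrices or (z, y, x) arrays")
  if (!is.numeric(pixel_size) || length(pixel_size) != 1L ||
      !is.finite(pixel_size) || pixel_size <= 0)
    stop("'pixel_size' must be a single positive number (um/pixel)")
  channels <- lapply(channels, function(ch) {
    if (is.matrix(ch)) ch <- array(ch, dim = c(1L, dim(ch)))
    if (!is.array(ch) || length(dim(ch)) != 3L)
      stop("each channel must be a matrix or a 3D (z, y, x) array")
    storage.mode(ch) <- "double"
    if (anyNA(ch) || any(!is.finite(ch)))
      stop("channel intensities must be finite")
    if (any(ch < 0))
      stop("channel intensities must be non-negative")
    ch
  })
  shp <- dim(channels[[1L]])
  for (ch in channels)
    if (!identical(dim(ch), shp))
      stop("all channels must share the same (z, y, x) shape")
  if (is.null(channel_names)) channel_names <- names(channels)
  if (is.null(channel_names))
    channel_names <- paste0("ch", seq_along(channels))
  if (length(channel_names) != length(channels) || anyDuplicated(channel_names))
    stop("'channel_names' must be unique and match the number of channels")
  names(channels) <- channel_names
  structure(
    list(channels = channels, pixel_size = pixel_size,
         channel_names = channel_names),
    class = "multichannel_image"
  )
}

#' @export
print.multichannel_image <- function(x, ...) {
  d <- dim(x$channels[[1L]])
  cat(sprintf(
    "<multichannel_image> %d channel(s) [%s], %d z, %d x %d px, %.4g um/px\n",
    length(x$channels), paste(x$channel_names, collapse = ", "),
    d[1L], d[2L], d[3L], x$pixel_size))
  invisible(x)
}

#' Number of z-slices of a multichannel image
#' @param image a `multichannel_image`
#' @return integer z-depth (1 for a plain 2D image)
#' @export
n_slices <- function(image) {
  stopifnot(inherits(image, "multichannel_image"))
  dim(image$channels[[1L]])[1L]
}

#' Extract one channel as a 2D matrix
#'
#' For z-stacks the image must be projected first (see [max_project()]);
#' requesting a 2D matrix from a stack with more than one slice is an error.
#'
#' @param image a `multichannel_image`
#' @param channel channel name or index
#' @return numeric matrix (rows = y, columns = x)
#' @export
get_channel <- function(image, channel) {
  stopifnot(inherits(image, "multichannel_image"))
  if (is.character(channel)) {
    if (!channel %in% image$channel_names)
      stop(sprintf("channel '%s' not found (have: %s)", channel,
                   paste(image$channel_names, collapse = ", ")))
  } else if (channel < 1L || channel > length(image$channels)) {
    stop("channel index out of range")
  }
  ch <- image$channels[[channel]]
  if (dim(ch)[1L] > 1L)
    stop("channel has multiple z-slices; apply max_project() first")
  matrix(ch[1L, , ], dim(ch)[2L], dim(ch)[3L])
}

#' Maximum-intensity projection of a z-stack
#'
#' Collapses the z dimension of every channel by taking, at each (y, x)
#' position, the maximum intensity over all slices. A single-slice image is
#' returned unchanged (up to container normalisation). The pixel size is
#' preserved.
#'
#' @param image a `multichannel_image` with z-depth >= 1
#' @return a `multichannel_image` with z-depth 1
#' @export
max_project <- function(image) {
  stopifnot(inherits(image, "multichannel_image"))
  nz <- n_slices(image)
  if (nz < 1L) stop("empty stack: no z-slices to project")
  channels <- lapply(image$channels, function(ch) {
    d <- dim(ch)
    out <- matrix(ch[1L, , ], d[2L], d[3L])
    if (d[1L] > 1L)
      for (z in 2L:d[1L]) out <- pmax(out, matrix(ch[z, , ], d[2L], d[3L]))
    out
  })
  multichannel_image(channels, image$pixel_size, image$channel_names)
}
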