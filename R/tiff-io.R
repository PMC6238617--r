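# Minimal baseline TIFF codec.
#
# The deployment environment ships no TIFF-capable R package, so the package
# carries its own reader/writer for the subset of TIFF 6.0 it needs:
# uncompressed single-sample (greyscale) images, multi-page, 8/16/32-bit
# unsigned integer or 32-bit IEEE float samples, strip-organised. The writer
# emits little-endian files; the reader accepts either byte order.
#
# Physical pixel size is stored twice: in the standard XResolution /
# YResolution / ResolutionUnit tags (pixels per centimetre) and, at full
# precision, in an ImageDescription key-value block that also records the
# channel/z page layout:
#
#   polcoloc
#   pixel_size_um=0.08
#   channels=nucleus,antigen,lamp1
#   n_z=1
#
# Pages are ordered channel-major: all z-slices of channel 1, then channel 2.

.u16 <- function(x) writeBin(as.integer(x), raw(), size = 2L, endian = "little")

.u32 <- function(x) {
  # doubles up to 2^32-1; as.integer would overflow at 2^31
  x <- as.numeric(x)
  out <- raw(4L * length(x))
  for (i in seq_along(x)) {
    lo <- x[i] %% 65536
    hi <- x[i] %/% 65536
    out[(4L * i - 3L):(4L * i)] <-
      c(.u16(lo), .u16(hi))
  }
  out
}

.tiff_entry <- function(tag, type, count, value_raw) {
  # value_raw must be exactly 4 bytes (left-justified inline value or offset)
  c(.u16(tag), .u16(type), .u32(count), value_raw)
}

.inline_short <- function(v) c(.u16(v), as.raw(c(0, 0)))

#' Write a multi-channel image as a multi-page TIFF
#'
#' One greyscale page per channel and z-slice (channel-major order).
#' Intensities are written as 64-bit floats by default, which round-trips
#' R's doubles exactly; `"float32"` halves the file size, and `"uint16"`
#' rounds and clamps to the 16-bit unsigned range at export time only.
#' The physical pixel size is recorded in the resolution tags and, at full
#' precision, in the ImageDescription, together with the channel names and
#' z-depth so that [read_image()] round-trips the container exactly.
#'
#' @param image a [multichannel_image()]
#' @param path output file path
#' @param dtype `"float64"` (default), `"float32"` or `"uint16"`
#' @return `path`, invisibly
#' @export
write_image <- function(image, path,
                        dtype = c("float64", "float32", "uint16")) {
  stopifnot(inherits(image, "multichannel_image"))
  dtype <- match.arg(dtype)
  d <- dim(image$channels[[1L]])
  nz <- d[1L]; h <- d[2L]; w <- d[3L]
  bytes_px <- switch(dtype, float64 = 8L, float32 = 4L, uint16 = 2L)
  bits <- 8L * bytes_px
  fmt <- if (dtype == "uint16") 1L else 3L  # SampleFormat

  pages <- list()
  for (ci in seq_along(image$channels)) {
    ch <- image$channels[[ci]]
    for (z in seq_len(nz)) {
      m <- matrix(ch[z, , ], h, w)
      v <- as.numeric(t(m))  # TIFF strips are row-major
      pages[[length(pages) + 1L]] <-
        if (dtype == "uint16") {
          writeBin(as.integer(pmin(pmax(round(v), 0), 65535)), raw(),
                   size = 2L, endian = "little")
        } else {
          writeBin(v, raw(), size = bytes_px, endian = "little")
        }
    }
  }
  n_pages <- length(pages)
  page_bytes <- h * w * bytes_px

  desc <- paste0(
    "polcoloc\n",
    sprintf("pixel_size_um=%.17g\n", image$pixel_size),
    "channels=", paste(image$channel_names, collapse = ","), "\n",
    sprintf("n_z=%d\n", nz))
  desc_raw <- c(charToRaw(desc), as.raw(0L))
  if (length(desc_raw) %% 2L == 1L) desc_raw <- c(desc_raw, as.raw(0L))

  # pixels per centimetre as a rational with denominator 1000
  res_num <- round(10000 / image$pixel_size * 1000)
  res_raw <- c(.u32(res_num), .u32(1000))

  # layout: header | page data ... | description | resolution | IFDs
  data_off <- 8 + c(0, cumsum(rep(page_bytes, n_pages)))[seq_len(n_pages)]
  desc_off <- 8 + n_pages * page_bytes
  res_off <- desc_off + length(desc_raw)
  ifd0_off <- res_off + 8

  ifds <- list()
  off <- ifd0_off
  ifd_offsets <- numeric(n_pages)
  for (p in seq_len(n_pages)) {
    entries <- list(
      .tiff_entry(256L, 4L, 1L, .u32(w)),          # ImageWidth
      .tiff_entry(257L, 4L, 1L, .u32(h)),          # ImageLength
      .tiff_entry(258L, 3L, 1L, .inline_short(bits)),
      .tiff_entry(259L, 3L, 1L, .inline_short(1L)),     # no compression
      .tiff_entry(262L, 3L, 1L, .inline_short(1L)))     # BlackIsZero
    if (p == 1L)
      entries <- c(entries, list(
        .tiff_entry(270L, 2L, length(desc_raw), .u32(desc_off))))
    entries <- c(entries, list(
      .tiff_entry(273L, 4L, 1L, .u32(data_off[p])),     # StripOffsets
      .tiff_entry(277L, 3L, 1L, .inline_short(1L)),     # SamplesPerPixel
      .tiff_entry(278L, 4L, 1L, .u32(h)),               # RowsPerStrip
      .tiff_entry(279L, 4L, 1L, .u32(page_bytes)),      # StripByteCounts
      .tiff_entry(282L, 5L, 1L, .u32(res_off)),         # XResolution
      .tiff_entry(283L, 5L, 1L, .u32(res_off)),         # YResolution
      .tiff_entry(296L, 3L, 1L, .inline_short(3L)),     # unit = cm
      .tiff_entry(339L, 3L, 1L, .inline_short(fmt))))   # SampleFormat
    ifd_offsets[p] <- off
    ifd_raw <- c(.u16(length(entries)), do.call(c, entries))
    off <- off + length(ifd_raw) + 4L  # + next-IFD pointer
    ifds[[p]] <- ifd_raw
  }

  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(c(charToRaw("II"), .u16(42L), .u32(ifd0_off)), con)
  for (p in seq_len(n_pages)) writeBin(pages[[p]], con)
  writeBin(desc_raw, con)
  writeBin(res_raw, con)
  for (p in seq_len(n_pages)) {
    nxt <- if (p < n_pages) ifd_offsets[p + 1L] else 0
    writeBin(c(ifds[[p]], .u32(nxt)), con)
  }
  invisible(path)
}

.read_uint <- function(bytes, size, endian) {
  n <- length(bytes) %/% size
  if (size == 1L) return(as.integer(bytes))
  if (size == 2L)
    return(readBin(bytes, "integer", n = n, size = 2L, endian = endian,
                   signed = FALSE))
  v <- readBin(bytes, "integer", n = n, size = 4L, endian = endian)
  ifelse(v < 0, v + 2^32, v)
}

.tiff_type_size <- c(1L, 1L, 2L, 4L, 8L, 1L, 1L, 2L, 4L, 8L, 4L, 8L)

#' Read a single- or multi-page TIFF into a multichannel image
#'
#' Supports the uncompressed greyscale subset written by [write_image()]
#' plus generic baseline files (8/16/32-bit unsigned or 32-bit float,
#' strip-organised, either byte order). Page layout and pixel size are
#' taken from the polcoloc ImageDescription block when present; otherwise
#' each page becomes one channel and the pixel size comes from the
#' resolution tags. An explicit `pixel_size` argument overrides file
#' metadata (with a warning when both exist). Negative float intensities
#' are clipped to zero on import.
#'
#' @param path TIFF file path
#' @param pixel_size optional pixel-size override, um/pixel
#' @param channel_names optional channel names override
#' @param n_z optional z-depth; pages are interpreted channel-major
#' @return a [multichannel_image()]
#' @export
read_image <- function(path, pixel_size = NULL, channel_names = NULL,
                       n_z = NULL) {
  if (!file.exists(path)) stop(sprintf("cannot read '%s': no such file", path))
  bytes <- readBin(path, "raw", n = file.info(path)$size)
  if (length(bytes) < 8L) stop(sprintf("'%s' is not a TIFF file", path))
  order_tag <- rawToChar(bytes[1:2])
  endian <- if (order_tag == "II") "little"
            else if (order_tag == "MM") "big"
            else stop(sprintf("'%s' is not a TIFF file (bad byte order mark)",
                              path))
  if (.read_uint(bytes[3:4], 2L, endian) != 42L)
    stop(sprintf("'%s' is not a TIFF file (bad magic)", path))

  ifd_off <- .read_uint(bytes[5:8], 4L, endian)
  pages <- list()
  meta_desc <- NULL
  meta_res <- NULL
  meta_unit <- 2L
  while (ifd_off != 0) {
    n_entries <- .read_uint(bytes[ifd_off + 1:2], 2L, endian)
    tags <- list()
    for (e in seq_len(n_entries)) {
      base <- ifd_off + 2L + (e - 1L) * 12L
      tag <- .read_uint(bytes[base + 1:2], 2L, endian)
      type <- .read_uint(bytes[base + 3:4], 2L, endian)
      count <- .read_uint(bytes[base + 5:8], 4L, endian)
      tsize <- .tiff_type_size[type]
      nbytes <- tsize * count
      vraw <- if (nbytes <= 4L) {
        bytes[base + 9:(8L + max(nbytes, 1L))]
      } else {
        voff <- .read_uint(bytes[base + 9:12], 4L, endian)
        bytes[voff + seq_len(nbytes)]
      }
      tags[[as.character(tag)]] <- list(type = type, count = count, raw = vraw)
    }
    getv <- function(tag, default = NULL) {
      t <- tags[[as.character(tag)]]
      if (is.null(t)) return(default)
      switch(as.character(t$type),
             "1" = .read_uint(t$raw, 1L, endian),
             "2" = {  # ASCII, NUL-terminated
               nul <- which(t$raw == as.raw(0L))
               end <- if (length(nul) > 0L) nul[1L] - 1L else length(t$raw)
               rawToChar(t$raw[seq_len(end)])
             },
             "3" = .read_uint(t$raw, 2L, endian),
             "4" = .read_uint(t$raw, 4L, endian),
             "5" = {  # RATIONAL pairs
               v <- .read_uint(t$raw, 4L, endian)
               v[seq(1L, length(v), 2L)] / v[seq(2L, length(v), 2L)]
             },
             "11" = readBin(t$raw, "double", n = t$count, size = 4L,
                            endian = endian),
             stop(sprintf("unsupported TIFF value type %d", t$type)))
    }
    w <- getv(256L); h <- getv(257L)
    if (is.null(w) || is.null(h)) stop("TIFF page lacks image dimensions")
    bits <- getv(258L, 8L)[1L]
    if (getv(259L, 1L) != 1L)
      stop("compressed TIFF not supported; re-export uncompressed")
    if (getv(277L, 1L) != 1L)
      stop("only single-sample (greyscale) TIFF pages are supported")
    fmt <- getv(339L, 1L)[1L]
    offs <- getv(273L); cnts <- getv(279L)
    if (is.null(offs)) stop("TIFF page lacks strip offsets")
    if (is.null(cnts)) cnts <- rep(w * h * bits / 8 / length(offs),
                                   length(offs))
    praw <- do.call(c, lapply(seq_along(offs),
                              function(i) bytes[offs[i] + seq_len(cnts[i])]))
    v <- if (fmt == 3L) {
      if (!bits %in% c(32L, 64L))
        stop("only 32- or 64-bit float TIFF samples are supported")
      readBin(praw, "double", n = w * h, size = bits / 8L, endian = endian)
    } else {
      .read_uint(praw, as.integer(bits / 8L), endian)
    }
    pages[[length(pages) + 1L]] <- matrix(as.numeric(v), h, w, byrow = TRUE)
    if (is.null(meta_desc)) meta_desc <- getv(270L)
    if (is.null(meta_res)) meta_res <- getv(282L)
    meta_unit <- getv(296L, meta_unit)
    ifd_off <- .read_uint(
      bytes[ifd_off + 2L + n_entries * 12L + 1:4], 4L, endian)
  }
  if (length(pages) == 0L) stop(sprintf("'%s' contains no image pages", path))

  # resolve metadata
  meta <- list()
  if (!is.null(meta_desc) && startsWith(meta_desc, "polcoloc")) {
    for (line in strsplit(meta_desc, "\n")[[1L]][-1L]) {
      kv <- strsplit(line, "=", fixed = TRUE)[[1L]]
      if (length(kv) == 2L) meta[[kv[1L]]] <- kv[2L]
    }
  }
  file_px <- NULL
  if (!is.null(meta$pixel_size_um)) {
    file_px <- as.numeric(meta$pixel_size_um)
  } else if (!is.null(meta_res) && meta_res[1L] > 0) {
    file_px <- switch(as.character(meta_unit),
                      "2" = 25400 / meta_res[1L],  # inch
                      "3" = 10000 / meta_res[1L],  # cm
                      NULL)
  }
  if (!is.null(pixel_size)) {
    if (!is.null(file_px) && abs(file_px - pixel_size) > 1e-9)
      warning(sprintf(
        "pixel size override %.4g um/px replaces file metadata %.4g um/px",
        pixel_size, file_px))
    px <- pixel_size
  } else if (!is.null(file_px)) {
    px <- file_px
  } else {
    stop(sprintf(
      "'%s' carries no pixel-size metadata; pass pixel_size= explicitly",
      path))
  }

  nz <- if (!is.null(n_z)) as.integer(n_z)
        else if (!is.null(meta$n_z)) as.integer(meta$n_z)
        else 1L
  if (length(pages) %% nz != 0L)
    stop(sprintf("page count %d is not a multiple of n_z = %d: axis layout ambiguous",
                 length(pages), nz))
  n_ch <- length(pages) %/% nz
  if (is.null(channel_names)) {
    channel_names <- if (!is.null(meta$channels))
      strsplit(meta$channels, ",", fixed = TRUE)[[1L]]
    else paste0("ch", seq_len(n_ch))
  }
  if (length(channel_names) != n_ch)
    stop(sprintf("%d channel names for %d channels: axis layout ambiguous",
                 length(channel_names), n_ch))
  channels <- vector("list", n_ch)
  for (ci in seq_len(n_ch)) {
    arr <- array(0, dim = c(nz, nrow(pages[[1L]]), ncol(pages[[1L]])))
    for (z in seq_len(nz)) arr[z, , ] <- pmax(pages[[(ci - 1L) * nz + z]], 0)
    channels[[ci]] <- arr
  }
  multichannel_image(channels, px, channel_names)
}
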