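# Minimal baseline TIFF 6.0 codec (grayscale, uncompressed, multi-page).
#
# No TIFF package exists in the supported dependency set, so the package
# carries its own small codec. Scope is deliberately narrow: single-sample
# grayscale, no compression, little-endian output. The writer emits 64-bit
# IEEE float samples (SampleFormat = 3) so that write -> read round-trips R
# doubles bit-identically; the reader additionally accepts 8/16/32-bit
# unsigned integer and 32-bit float pages (big- or little-endian) so
# externally produced stacks can be loaded.

TIFF_TAGS <- c(width = 256L, length = 257L, bits = 258L, compression = 259L,
               photometric = 262L, strip_offsets = 273L,
               samples_per_pixel = 277L, rows_per_strip = 278L,
               strip_bytecounts = 279L, sample_format = 339L)

#' Write a grayscale multi-page TIFF
#'
#' Pages are written uncompressed as 64-bit float samples so that
#' [read_tiff()] returns the array bit-identically.
#'
#' @param data numeric matrix (one page) or `pages x rows x cols` array.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_tiff <- function(data, path) {
  if (is.matrix(data)) data <- array(data, c(1L, dim(data)))
  stopifnot(is.array(data), length(dim(data)) == 3L)
  n <- dim(data)[1L]; h <- dim(data)[2L]; w <- dim(data)[3L]
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw("II"), con)
  writeBin(42L, con, size = 2L, endian = "little")
  # layout: header (8) | page strips | IFD chain
  strip_bytes <- as.numeric(w) * h * 8
  strip_off <- 8 + (seq_len(n) - 1) * strip_bytes
  ifd_size <- 2 + 10 * 12 + 4            # entry count + 10 entries + next ptr
  ifd0 <- 8 + n * strip_bytes
  ifd_off <- ifd0 + (seq_len(n) - 1) * ifd_size
  writeBin(as.integer(ifd0), con, size = 4L, endian = "little")
  for (i in seq_len(n)) {
    page <- t(matrix(data[i, , ], h, w))   # row-major sample order
    writeBin(as.vector(page), con, size = 8L, endian = "little")
  }
  entry <- function(tag, type, count, value) {
    writeBin(as.integer(tag), con, size = 2L, endian = "little")
    writeBin(as.integer(type), con, size = 2L, endian = "little")
    writeBin(as.integer(count), con, size = 4L, endian = "little")
    if (type == 3L) {  # SHORT: left-justified in the 4-byte value field
      writeBin(as.integer(value), con, size = 2L, endian = "little")
      writeBin(0L, con, size = 2L, endian = "little")
    } else {
      writeBin(as.integer(value), con, size = 4L, endian = "little")
    }
  }
  for (i in seq_len(n)) {
    writeBin(10L, con, size = 2L, endian = "little")
    entry(256L, 4L, 1L, w)                    # ImageWidth
    entry(257L, 4L, 1L, h)                    # ImageLength
    entry(258L, 3L, 1L, 64L)                  # BitsPerSample
    entry(259L, 3L, 1L, 1L)                   # Compression = none
    entry(262L, 3L, 1L, 1L)                   # Photometric = BlackIsZero
    entry(273L, 4L, 1L, strip_off[i])         # StripOffsets
    entry(277L, 3L, 1L, 1L)                   # SamplesPerPixel
    entry(278L, 4L, 1L, h)                    # RowsPerStrip
    entry(279L, 4L, 1L, strip_bytes)          # StripByteCounts
    entry(339L, 3L, 1L, 3L)                   # SampleFormat = IEEE float
    nxt <- if (i < n) ifd_off[i + 1L] else 0
    writeBin(as.integer(nxt), con, size = 4L, endian = "little")
  }
  invisible(path)
}

#' Read a grayscale multi-page TIFF
#'
#' @param path TIFF file path.
#' @return numeric array `pages x rows x cols`.
#' @export
read_tiff <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- readBin(path, "raw", n = file.size(path))
  if (length(raw) < 8L) stop("not a TIFF file (truncated header): ", path)
  endian <- if (rawToChar(raw[1:2]) == "II") "little"
            else if (rawToChar(raw[1:2]) == "MM") "big"
            else stop("not a TIFF file (bad byte-order mark): ", path)
  u <- function(off, size, n = 1L)
    readBin(raw[(off + 1):(off + size * n)], "integer", n = n, size = size,
            signed = FALSE, endian = endian)
  u4 <- function(off, n = 1L)   # unsigned 32-bit without sign overflow
    vapply(seq_len(n), function(i) {
      b <- as.numeric(raw[(off + 4 * (i - 1) + 1):(off + 4 * i)])
      if (endian == "little") sum(b * 256^(0:3)) else sum(b * 256^(3:0))
    }, numeric(1))
  if (u(2, 2) != 42L) stop("not a TIFF file (bad magic): ", path)
  ifd <- u4(4)
  pages <- list()
  while (ifd != 0) {
    n_entries <- u(ifd, 2)
    tags <- list()
    for (e in seq_len(n_entries)) {
      off <- ifd + 2 + (e - 1) * 12
      tag <- u(off, 2); type <- u(off + 2, 2); count <- u4(off + 4)
      tsize <- c(`1` = 1L, `2` = 1L, `3` = 2L, `4` = 4L)[as.character(type)]
      if (is.na(tsize)) next                     # unsupported type: skip tag
      val_off <- if (tsize * count <= 4) off + 8 else u4(off + 8)
      vals <- if (type == 4L) u4(val_off, count) else u(val_off, tsize, count)
      tags[[as.character(tag)]] <- vals
    }
    g <- function(tag, default = NULL) tags[[as.character(tag)]] %||% default
    w <- g(256L); h <- g(257L)
    if (is.null(w) || is.null(h)) stop("TIFF page missing dimensions: ", path)
    if ((g(259L, 1L))[1L] != 1L) stop("compressed TIFF not supported: ", path)
    spp <- (g(277L, 1L))[1L]
    if (spp != 1L) stop("only single-sample grayscale TIFF supported: ", path)
    bits <- (g(258L, 8L))[1L]
    fmt <- (g(339L, 1L))[1L]
    offsets <- g(273L); counts <- g(279L)
    if (is.null(offsets)) stop("TIFF page missing strip offsets: ", path)
    bytes_per <- bits / 8
    vals <- unlist(lapply(seq_along(offsets), function(i) {
      nb <- if (!is.null(counts)) counts[i] else w * h * bytes_per
      o <- offsets[i]
      if (fmt == 3L) {
        readBin(raw[(o + 1):(o + nb)], "numeric", n = nb / bytes_per,
                size = bytes_per, endian = endian)
      } else if (bits %in% c(8L, 16L)) {
        readBin(raw[(o + 1):(o + nb)], "integer", n = nb / bytes_per,
                size = bytes_per, signed = FALSE, endian = endian)
      } else if (bits == 32L) {
        u4(o, nb / 4)
      } else stop("unsupported TIFF sample layout (bits=", bits, ")")
    }))
    if (length(vals) != w * h) stop("TIFF strip data inconsistent: ", path)
    pages[[length(pages) + 1L]] <- t(matrix(vals, w, h))   # row-major strips
    ifd <- u4(ifd + 2 + n_entries * 12)
  }
  if (!length(pages)) stop("TIFF contains no pages: ", path)
  hw <- lapply(pages, dim)
  if (length(unique(vapply(hw, paste, "", collapse = "x"))) != 1L)
    stop("TIFF pages have inconsistent shapes: ", path)
  out <- array(0, c(length(pages), nrow(pages[[1L]]), ncol(pages[[1L]])))
  for (i in seq_along(pages)) out[i, , ] <- pages[[i]]
  out
}

#' Read a TIFF stack with acquisition metadata
#'
#' Page order is preserved as frame/slice order. Pixel size and step are
#' supplied by the caller (config/CLI values take precedence over anything a
#' file might claim, since acquisition settings are typically recorded in
#' protocols rather than reliably in file tags).
#'
#' @param path multi-page TIFF path.
#' @inheritParams image_stack
#' @return an [image_stack()].
#' @export
read_stack <- function(path, axis_kind = c("time", "z"),
                       pixel_size_um, step) {
  axis_kind <- match.arg(axis_kind)
  arr <- read_tiff(path)
  image_stack(arr, axis_kind = axis_kind,
              pixel_size_um = pixel_size_um, step = step)
}

#' Write an ImageStack (or array) to TIFF
#' @param stack an [image_stack()] or numeric array/matrix.
#' @param path output path.
#' @export
write_stack <- function(stack, path) {
  data <- if (inherits(stack, "ImageStack")) stack$data else stack
  write_tiff(data, path)
}
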