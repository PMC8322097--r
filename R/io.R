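# Image file I/O.
#
# Grayscale images are read from single-channel TIFF (8/16-bit unsigned
# integer or 32-bit float, uncompressed), ASCII PGM (P2) or headerless CSV.
# No TIFF package ships with base R, so a minimal baseline-TIFF codec is
# included here; it deliberately rejects anything beyond the simple
# single-channel case (compression, multi-page, palette, RGB).

.tiff_type_size <- c(`1` = 1L, `2` = 1L, `3` = 2L, `4` = 4L)

.tiff_read_values <- function(raw, off, type, count, endian) {
  size <- .tiff_type_size[as.character(type)]
  if (is.na(size)) return(NULL)
  total <- size * count
  # values of 4 bytes or fewer are stored inline in the IFD entry
  at <- if (total <= 4L) off else {
    readBin(raw[(off + 1L):(off + 4L)], "integer", 1L, 4L, endian = endian)
  }
  bytes <- raw[(at + 1L):(at + total)]
  if (type %in% c(1L, 2L)) {
    as.numeric(readBin(bytes, "integer", count, 1L, signed = FALSE))
  } else if (type == 3L) {
    as.numeric(readBin(bytes, "integer", count, 2L, signed = FALSE,
                       endian = endian))
  } else {
    as.numeric(readBin(bytes, "integer", count, 4L, endian = endian))
  }
}

#' Read a grayscale TIFF image
#'
#' Minimal reader for single-channel baseline TIFF: uncompressed, one page,
#' 8- or 16-bit unsigned integer or 32-bit IEEE float samples, either byte
#' order. Anything else (compressed, multi-page, multi-sample) is rejected
#' with an informative error.
#'
#' @param path path to a `.tif`/`.tiff` file.
#' @param pixel_size_nm pixel size metadata attached to the result.
#' @return A [grayscale_image].
#' @export
read_tiff_gray <- function(path, pixel_size_nm = 73) {
  raw <- readBin(path, "raw", file.size(path))
  if (length(raw) < 8L) stop("not a TIFF file (too short): ", path, call. = FALSE)
  order_tag <- rawToChar(raw[1:2])
  endian <- switch(order_tag, II = "little", MM = "big",
                   stop("not a TIFF file (bad byte-order mark): ", path,
                        call. = FALSE))
  magic <- readBin(raw[3:4], "integer", 1L, 2L, signed = FALSE, endian = endian)
  if (magic != 42L) stop("not a TIFF file (bad magic number): ", path, call. = FALSE)
  ifd_off <- readBin(raw[5:8], "integer", 1L, 4L, endian = endian)

  n_entries <- readBin(raw[(ifd_off + 1L):(ifd_off + 2L)], "integer", 1L, 2L,
                       signed = FALSE, endian = endian)
  tags <- list()
  for (e in seq_len(n_entries)) {
    off <- ifd_off + 2L + (e - 1L) * 12L
    tag <- readBin(raw[(off + 1L):(off + 2L)], "integer", 1L, 2L,
                   signed = FALSE, endian = endian)
    type <- readBin(raw[(off + 3L):(off + 4L)], "integer", 1L, 2L,
                    signed = FALSE, endian = endian)
    count <- readBin(raw[(off + 5L):(off + 8L)], "integer", 1L, 4L,
                     endian = endian)
    tags[[as.character(tag)]] <- .tiff_read_values(raw, off + 8L, type, count,
                                                   endian)
  }
  next_ifd <- readBin(raw[(ifd_off + 2L + n_entries * 12L + 1L):
                          (ifd_off + 2L + n_entries * 12L + 4L)],
                      "integer", 1L, 4L, endian = endian)
  if (next_ifd != 0L) {
    stop("multi-page TIFF not supported: ", path, call. = FALSE)
  }

  get1 <- function(tag, default = NULL) {
    v <- tags[[as.character(tag)]]
    if (is.null(v)) default else v[1]
  }
  width <- get1(256); height <- get1(257)
  if (is.null(width) || is.null(height)) {
    stop("TIFF missing image dimensions: ", path, call. = FALSE)
  }
  if (get1(259, 1) != 1) stop("compressed TIFF not supported: ", path, call. = FALSE)
  if (get1(277, 1) != 1) stop("multi-channel TIFF not supported (samples per pixel > 1): ",
                              path, call. = FALSE)
  bits <- get1(258, 1)
  fmt <- get1(339, 1)  # 1 = unsigned int, 3 = IEEE float
  strip_offsets <- tags[["273"]]
  strip_counts <- tags[["279"]]
  if (is.null(strip_offsets)) stop("TIFF missing strip offsets: ", path, call. = FALSE)
  if (is.null(strip_counts)) {
    strip_counts <- width * height * bits / 8  # single strip fallback
  }
  data <- raw(0)
  for (s in seq_along(strip_offsets)) {
    a <- strip_offsets[s]
    data <- c(data, raw[(a + 1L):(a + strip_counts[s])])
  }
  n_px <- width * height
  vals <- if (fmt == 3 && bits == 32) {
    readBin(data, "double", n_px, 4L, endian = endian)
  } else if (fmt == 1 && bits == 8) {
    as.numeric(readBin(data, "integer", n_px, 1L, signed = FALSE))
  } else if (fmt == 1 && bits == 16) {
    as.numeric(readBin(data, "integer", n_px, 2L, signed = FALSE,
                       endian = endian))
  } else {
    stop(sprintf("unsupported TIFF sample layout (%d-bit, format %d): %s",
                 bits, fmt, path), call. = FALSE)
  }
  # TIFF pixel data are row-major; transpose into the row/column matrix
  px <- t(matrix(vals, nrow = width, ncol = height))
  grayscale_image(px, pixel_size_nm = pixel_size_nm)
}

#' Write a grayscale TIFF image
#'
#' Writes an uncompressed, single-strip, little-endian baseline TIFF.
#' Integer-valued images in \[0, 65535\] are written as 16-bit unsigned
#' integers; anything else as 32-bit IEEE float.
#'
#' @param img a [grayscale_image] or numeric matrix.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_tiff_gray <- function(img, path) {
  img <- as_grayscale_image(img)
  px <- img$pixels
  h <- nrow(px); w <- ncol(px)
  v <- as.vector(t(px))  # row-major
  as_int <- all(v == round(v)) && all(v >= 0) && all(v <= 65535)
  bits <- if (as_int) 16L else 32L
  fmt <- if (as_int) 1L else 3L
  bytes_per <- bits / 8L
  n_tags <- 10L
  data_off <- 8L + 2L + n_tags * 12L + 4L

  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw("II"), con)
  writeBin(42L, con, 2L, endian = "little")
  writeBin(8L, con, 4L, endian = "little")  # IFD immediately after header
  writeBin(n_tags, con, 2L, endian = "little")
  entry <- function(tag, type, count, value) {
    writeBin(as.integer(tag), con, 2L, endian = "little")
    writeBin(as.integer(type), con, 2L, endian = "little")
    writeBin(as.integer(count), con, 4L, endian = "little")
    if (type == 3L) {  # SHORT: left-justified in the 4-byte value field
      writeBin(as.integer(value), con, 2L, endian = "little")
      writeBin(0L, con, 2L, endian = "little")
    } else {
      writeBin(as.integer(value), con, 4L, endian = "little")
    }
  }
  entry(256L, 4L, 1L, w)                     # ImageWidth
  entry(257L, 4L, 1L, h)                     # ImageLength
  entry(258L, 3L, 1L, bits)                  # BitsPerSample
  entry(259L, 3L, 1L, 1L)                    # Compression: none
  entry(262L, 3L, 1L, 1L)                    # Photometric: BlackIsZero
  entry(273L, 4L, 1L, data_off)              # StripOffsets
  entry(277L, 3L, 1L, 1L)                    # SamplesPerPixel
  entry(278L, 4L, 1L, h)                     # RowsPerStrip: single strip
  entry(279L, 4L, 1L, w * h * bytes_per)     # StripByteCounts
  entry(339L, 3L, 1L, fmt)                   # SampleFormat
  writeBin(0L, con, 4L, endian = "little")   # no further IFD
  if (as_int) {
    # low-order two bytes of the signed int reproduce the unsigned value
    writeBin(as.integer(v), con, 2L, endian = "little")
  } else {
    writeBin(as.double(v), con, 4L, endian = "little")
  }
  invisible(path)
}

#' Read an ASCII PGM (P2) image
#'
#' @param path path to a `.pgm` file in the plain (P2) format.
#' @param pixel_size_nm pixel size metadata attached to the result.
#' @return A [grayscale_image].
#' @export
read_pgm <- function(path, pixel_size_nm = 73) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  tokens <- unlist(strsplit(paste(lines, collapse = " "), "[ \t]+"))
  tokens <- tokens[nzchar(tokens)]
  if (length(tokens) < 4L || tokens[1] != "P2") {
    stop("not an ASCII (P2) PGM file: ", path, call. = FALSE)
  }
  w <- as.integer(tokens[2]); h <- as.integer(tokens[3])
  vals <- as.numeric(tokens[-(1:4)])  # token 4 is maxval
  if (length(vals) != w * h) {
    stop("PGM pixel count mismatch in ", path, call. = FALSE)
  }
  px <- t(matrix(vals, nrow = w, ncol = h))  # stored row-major
  grayscale_image(px, pixel_size_nm = pixel_size_nm)
}

#' Write an ASCII PGM (P2) image
#'
#' Values are rounded to integers and clamped at 0; `maxval` is taken from
#' the data.
#'
#' @param img a [grayscale_image] or numeric matrix.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_pgm <- function(img, path) {
  img <- as_grayscale_image(img)
  px <- pmax(round(img$pixels), 0)
  maxval <- max(px, 1)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("P2", paste(ncol(px), nrow(px)), format(maxval, scientific = FALSE)), con)
  apply(px, 1L, function(row) {
    writeLines(paste(format(row, scientific = FALSE, trim = TRUE),
                     collapse = " "), con)
  })
  invisible(path)
}

#' Read a grayscale image file
#'
#' Dispatches on the file extension: `.tif`/`.tiff` ([read_tiff_gray]),
#' `.pgm` ([read_pgm]) or `.csv` (headerless numeric matrix).
#'
#' @param path image file path.
#' @param pixel_size_nm pixel size metadata attached to the result.
#' @return A [grayscale_image].
#' @export
read_image <- function(path, pixel_size_nm = 73) {
  if (!file.exists(path)) stop("image file not found: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    tif = ,
    tiff = read_tiff_gray(path, pixel_size_nm),
    pgm = read_pgm(path, pixel_size_nm),
    csv = {
      m <- as.matrix(utils::read.csv(path, header = FALSE))
      dimnames(m) <- NULL
      grayscale_image(m, pixel_size_nm = pixel_size_nm)
    },
    stop("unsupported image format '", ext, "': ", path, call. = FALSE)
  )
  img
}
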