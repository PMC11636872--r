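# Image input/output.
#
# The portable formats of record here are NetPBM PGM/PPM (ASCII P2/P3 and
# binary P5/P6): no PNG/JPEG codec package is guaranteed in the runtime, so
# PNM is the native on-disk format and PNG/JPEG are read opportunistically
# through the optional `png`/`jpeg` packages.

parse_pnm_header <- function(raw) {
  # returns list(magic, width, height, maxval, offset of pixel data)
  n <- length(raw)
  pos <- 1L
  tokens <- character(0)
  while (length(tokens) < 4L && pos <= n) {
    ch <- rawToChar(raw[pos])
    if (ch == "#") { # comment to end of line
      while (pos <= n && rawToChar(raw[pos]) != "\n") pos <- pos + 1L
      pos <- pos + 1L
    } else if (grepl("[[:space:]]", ch)) {
      pos <- pos + 1L
    } else {
      start <- pos
      while (pos <= n && !grepl("[[:space:]]", rawToChar(raw[pos])) &&
             rawToChar(raw[pos]) != "#") pos <- pos + 1L
      tokens <- c(tokens, rawToChar(raw[start:(pos - 1L)]))
    }
    if (length(tokens) == 4L) {
      # exactly one whitespace byte separates header from pixel data
      pos <- pos + 1L
      break
    }
  }
  if (length(tokens) < 4L) stop("truncated PNM header")
  list(magic = tokens[1], width = as.integer(tokens[2]),
       height = as.integer(tokens[3]), maxval = as.integer(tokens[4]),
       offset = pos)
}

#' Read a PGM/PPM image
#'
#' Supports ASCII (`P2`, `P3`) and binary (`P5`, `P6`) NetPBM files with
#' maxval up to 65535. Grayscale images are promoted to 3 channels.
#'
#' @param path file path.
#' @return an H x W x 3 array of values in `[0, 1]`.
#' @export
read_pnm <- function(path) {
  raw <- readBin(path, "raw", file.size(path))
  h <- parse_pnm_header(raw)
  npix <- h$width * h$height
  nch <- if (h$magic %in% c("P3", "P6")) 3L else 1L
  if (h$magic %in% c("P2", "P3")) {
    txt <- rawToChar(raw[h$offset:length(raw)])
    vals <- as.numeric(scan(text = txt, quiet = TRUE, comment.char = "#"))
  } else if (h$magic %in% c("P5", "P6")) {
    body <- raw[h$offset:length(raw)]
    if (h$maxval < 256) {
      vals <- as.numeric(as.integer(body[seq_len(npix * nch)]))
    } else {
      vals <- readBin(body, "integer", n = npix * nch, size = 2,
                      signed = FALSE, endian = "big")
    }
  } else {
    stop(sprintf("unsupported PNM magic '%s'", h$magic))
  }
  if (length(vals) < npix * nch) stop("truncated PNM pixel data")
  vals <- vals[seq_len(npix * nch)] / h$maxval
  # PNM stores row-major, channel-interleaved
  if (nch == 3L) {
    m <- matrix(vals, nrow = 3L)
    arr <- array(0, dim = c(h$height, h$width, 3L))
    for (c in 1:3) arr[, , c] <- matrix(m[c, ], nrow = h$height, byrow = TRUE)
  } else {
    g <- matrix(vals, nrow = h$height, byrow = TRUE)
    arr <- array(rep(g, 3L), dim = c(h$height, h$width, 3L))
  }
  arr
}

#' Write an image as ASCII PPM (color) or PGM (grayscale)
#'
#' @param image H x W x 3 array in `[0, 1]` (written as `P3`), or an H x W
#'   matrix in `[0, 1]` (written as `P2`).
#' @param path destination path.
#' @param maxval maximum sample value (255 for 8-bit, 65535 for label maps).
#' @return `path`, invisibly.
#' @export
write_pnm <- function(image, path, maxval = 255L) {
  con <- file(path, "w")
  on.exit(close(con))
  if (is.matrix(image)) {
    writeLines(c("P2", paste(ncol(image), nrow(image)), as.character(maxval)), con)
    write(as.integer(round(t(image) * maxval)), con, ncolumns = 16L) # row-major
  } else {
    assert_image(image)
    H <- dim(image)[1]; W <- dim(image)[2]
    inter <- rbind(
      as.vector(t(image[, , 1])),
      as.vector(t(image[, , 2])),
      as.vector(t(image[, , 3]))
    )
    writeLines(c("P3", paste(W, H), as.character(maxval)), con)
    write(as.integer(round(inter * maxval)), con, ncolumns = 15L)
  }
  invisible(path)
}

#' Read an image file (PNM natively; PNG/JPEG if codecs are installed)
#'
#' @param path file path; format chosen by extension.
#' @return an H x W x 3 array in `[0, 1]`; grayscale promoted to 3 channels.
#' @export
read_image <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("ppm", "pgm", "pnm")) return(read_pnm(path))
  if (ext == "png") {
    if (!requireNamespace("png", quietly = TRUE))
      stop("reading PNG requires the 'png' package; use PPM/PGM instead")
    img <- png::readPNG(path)
  } else if (ext %in% c("jpg", "jpeg")) {
    if (!requireNamespace("jpeg", quietly = TRUE))
      stop("reading JPEG requires the 'jpeg' package; use PPM/PGM instead")
    img <- jpeg::readJPEG(path)
  } else {
    stop(sprintf("unsupported image extension '%s'", ext))
  }
  if (is.matrix(img)) img <- array(rep(img, 3L), dim = c(dim(img), 3L))
  if (dim(img)[3] > 3L) img <- img[, , 1:3, drop = FALSE] # drop alpha
  img
}

#' Write a binary mask as a 0/255 PGM file
#'
#' @param mask a `binary_mask` or 0/1 matrix.
#' @param path destination path.
#' @export
write_mask <- function(mask, path) {
  v <- if (inherits(mask, "binary_mask")) mask$values else mask
  assert_binary(v)
  write_pnm(v, path, maxval = 255L)
}

#' Read a 0/255 mask image into a 0/1 matrix
#'
#' Any pixel above half intensity is foreground.
#'
#' @param path file path of a PGM/PNM (or PNG if available) mask.
#' @return an H x W matrix of 0/1 integers.
#' @export
read_mask <- function(path) {
  arr <- read_image(path)
  (arr[, , 1] > 0.5) + 0L
}

#' Write a superpixel label map as a 16-bit PGM for inspection
#'
#' @param spmap a `superpixel_map`.
#' @param path destination path.
#' @export
write_label_map <- function(spmap, path) {
  write_pnm(spmap$labels / 65535, path, maxval = 65535L)
}
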