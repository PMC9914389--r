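# Image I/O substrate: PNG / JPEG via the png and jpeg packages, PPM / PGM
# via a minimal PNM codec (no installed package reads PNM). All images are
# 8-bit at the I/O boundary; RGB images are H x W x 3 numeric arrays of
# uint8 values, grayscale images are matrices with a "uint8" scale
# attribute (see grayImage()).

pnmReadToken <- function(raw, pos) {
  n <- length(raw)
  repeat {
    while (pos <= n && raw[pos] %in% as.raw(c(9L, 10L, 13L, 32L))) pos <- pos + 1L
    if (pos <= n && raw[pos] == as.raw(35L)) {            # '#' comment
      while (pos <= n && raw[pos] != as.raw(10L)) pos <- pos + 1L
    } else break
  }
  start <- pos
  while (pos <= n && !(raw[pos] %in% as.raw(c(9L, 10L, 13L, 32L)))) pos <- pos + 1L
  list(token = rawToChar(raw[start:(pos - 1L)]), pos = pos)
}

readPNM <- function(path) {
  raw <- readBin(path, "raw", file.info(path)$size)
  if (length(raw) < 2L) stop("truncated PNM file: ", path)
  magic <- rawToChar(raw[1:2])
  if (!magic %in% c("P2", "P3", "P5", "P6"))
    stop("unsupported PNM variant '", magic, "' in ", path)
  pos <- 3L
  hdr <- integer(3)
  for (i in 1:3) {
    tk <- pnmReadToken(raw, pos)
    hdr[i] <- suppressWarnings(as.integer(tk$token))
    if (is.na(hdr[i])) stop("malformed PNM header in ", path)
    pos <- tk$pos
  }
  w <- hdr[1]; h <- hdr[2]; maxval <- hdr[3]
  if (maxval > 255L)
    stop("unsupported format: ", path, " has bit depth > 8 (maxval ", maxval, ")")
  nch <- if (magic %in% c("P3", "P6")) 3L else 1L
  npx <- as.double(w) * h * nch
  if (magic %in% c("P5", "P6")) {
    pos <- pos + 1L                                       # single whitespace
    if (length(raw) - pos + 1L < npx) stop("truncated PNM payload in ", path)
    vals <- as.integer(raw[pos:(pos + npx - 1L)])
  } else {
    vals <- integer(npx)
    for (i in seq_len(npx)) {
      tk <- pnmReadToken(raw, pos)
      vals[i] <- suppressWarnings(as.integer(tk$token))
      pos <- tk$pos
    }
    if (anyNA(vals)) stop("malformed ASCII PNM payload in ", path)
  }
  if (nch == 1L) {
    grayImage(matrix(as.numeric(vals), h, w, byrow = TRUE), "uint8")
  } else {
    px <- array(0, c(h, w, 3L))
    m <- matrix(vals, nrow = 3L)                          # interleaved RGB
    for (k in 1:3) px[, , k] <- matrix(as.numeric(m[k, ]), h, w, byrow = TRUE)
    px
  }
}

writePNM <- function(img, path) {
  binary <- TRUE
  if (is.matrix(img)) {
    if (imageScale(img) != "uint8") img <- asUint8(img)
    raw <- as.raw(as.integer(t(img)))
    hdr <- sprintf("P5\n%d %d\n255\n", ncol(img), nrow(img))
  } else {
    m <- rbind(as.integer(t(img[, , 1])), as.integer(t(img[, , 2])),
               as.integer(t(img[, , 3])))
    raw <- as.raw(as.vector(m))
    hdr <- sprintf("P6\n%d %d\n255\n", ncol(img), nrow(img))
  }
  con <- file(path, "wb"); on.exit(close(con))
  writeBin(charToRaw(hdr), con)
  writeBin(raw, con)
  invisible(path)
}

pngBitDepth <- function(path) {
  hdr <- readBin(path, "raw", 26L)
  if (length(hdr) < 26L) stop("truncated PNG file: ", path)
  as.integer(hdr[25])                                     # IHDR bit-depth byte
}

#' Read a fundus-style image
#'
#' Reads PNG, JPEG, PPM or PGM (8 bits per channel). Color files yield an
#' H x W x 3 numeric array of uint8 values; grayscale files yield a
#' grayscale matrix with a `"uint8"` scale attribute. Alpha channels are
#' dropped.
#'
#' @param path path to the image file.
#' @return RGB array or grayscale image matrix, uint8 convention.
#' @export
readFundusImage <- function(path) {
  if (!file.exists(path)) stop("cannot read image: no such file '", path, "'")
  ext <- tolower(tools::file_ext(path))
  px <- switch(ext,
    png = {
      if (pngBitDepth(path) > 8L)
        stop("unsupported format: ", path, " is a >8-bit PNG")
      png::readPNG(path)
    },
    jpg = , jpeg = jpeg::readJPEG(path),
    ppm = , pgm = , pnm = return(readPNM(path)),
    stop("unsupported image format '.", ext, "' for ", path))
  px <- floor(px * 255 + 0.5)
  if (length(dim(px)) == 3L) {
    if (dim(px)[3] >= 3L) return(px[, , 1:3, drop = TRUE])
    px <- px[, , 1]
  }
  grayImage(px, "uint8")
}

#' Write an image or mask losslessly
#'
#' `writeFundusImage()` writes PNG (default) or binary PPM/PGM depending on
#' the file extension; PNG/PNM round-trips through [readFundusImage()] are
#' pixel-exact. `writeMask()` encodes a binary \{0,1\} mask as a
#' single-channel PNG with \{0,255\} values; `readMask()` reads any
#' two-valued image back, mapping the larger value to vessel (1).
#'
#' @param img RGB array or grayscale matrix (uint8 convention).
#' @param path output path; extension selects the format.
#' @return the path, invisibly.
#' @export
writeFundusImage <- function(img, path) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("ppm", "pgm", "pnm")) return(writePNM(img, path))
  if (ext != "png") stop("artifact outputs are written as PNG (or PPM/PGM)")
  if (is.matrix(img) && imageScale(img) != "uint8") img <- asUint8(img)
  png::writePNG(img / 255, path)
  invisible(path)
}

#' @rdname writeFundusImage
#' @param mask binary \{0,1\} matrix.
#' @export
writeMask <- function(mask, path) {
  if (!all(mask %in% c(0L, 1L))) stop("mask must be two-valued {0,1}")
  png::writePNG(matrix(as.numeric(mask), nrow(mask)), path)
  invisible(path)
}

#' @rdname writeFundusImage
#' @export
readMask <- function(path) {
  img <- readFundusImage(path)
  if (!is.matrix(img)) img <- grayImage(img[, , 1], "uint8")
  vals <- sort(unique(as.vector(img)))
  if (length(vals) > 2L)
    stop("mask file ", path, " is not two-valued (", length(vals), " levels)")
  out <- matrix(0L, nrow(img), ncol(img))
  out[img == vals[length(vals)]] <- 1L                    # larger value = vessel
  if (length(vals) == 1L && vals[1] == 0) out[] <- 0L
  out
}

#' Split an RGB image into its channel planes
#'
#' The green plane is the working channel for vessel extraction: vessels
#' show the strongest contrast against the retinal background there.
#'
#' @param img H x W x 3 uint8 RGB array.
#' @return named list of grayscale images `red`, `green`, `blue`.
#' @export
splitChannels <- function(img) {
  if (length(dim(img)) != 3L || dim(img)[3] != 3L)
    stop("'img' must be an H x W x 3 RGB array")
  list(red   = grayImage(img[, , 1], "uint8"),
       green = grayImage(img[, , 2], "uint8"),
       blue  = grayImage(img[, , 3], "uint8"))
}

#' Combine three channel planes back into an RGB array
#' @param red,green,blue grayscale uint8 images of equal size.
#' @return H x W x 3 numeric array.
#' @export
combineChannels <- function(red, green, blue) {
  stopifnotShape(red, green); stopifnotShape(red, blue)
  out <- array(0, c(dim(red), 3L))
  out[, , 1] <- red; out[, , 2] <- green; out[, , 3] <- blue
  out
}

#' 256-bin intensity histogram of a uint8 grayscale image
#'
#' @param img grayscale image on the uint8 scale.
#' @return integer vector `h` of length 256, `h[i + 1]` counting pixels of
#'   value i; `sum(h)` equals the pixel count.
#' @export
computeHistogram <- function(img) {
  if (imageScale(img) != "uint8")
    stop("computeHistogram() needs a uint8 image; convert with asUint8()")
  tabulate(as.integer(img) + 1L, nbins = 256L)
}
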