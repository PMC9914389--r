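# Internal helpers: image scale bookkeeping, matrix shifting, seeded RNG scope.

#' Construct a grayscale image matrix with a declared intensity scale
#'
#' Grayscale images are plain numeric matrices carrying a `scale` attribute,
#' either `"uint8"` (integer values in \[0, 255\]) or `"unit"` (reals in
#' \[0, 1\]). All pipeline-internal arithmetic runs on the unit scale; the
#' uint8 scale is the I/O and thresholding convention.
#'
#' @param pixels numeric matrix of intensities.
#' @param scale `"uint8"` or `"unit"`.
#' @return the matrix with its `scale` attribute set (class unchanged).
#' @export
grayImage <- function(pixels, scale = c("uint8", "unit")) {
  scale <- match.arg(scale)
  if (!is.matrix(pixels) || !is.numeric(pixels))
    stop("'pixels' must be a numeric matrix")
  rng <- range(pixels)
  if (scale == "uint8" && (rng[1] < 0 || rng[2] > 255))
    stop("uint8 image values must lie in [0, 255]")
  if (scale == "unit" && (rng[1] < -1e-12 || rng[2] > 1 + 1e-12))
    stop("unit-scale image values must lie in [0, 1]")
  attr(pixels, "scale") <- scale
  pixels
}

#' Query the declared scale of a grayscale image
#' @param img grayscale image matrix.
#' @return `"uint8"` or `"unit"`; matrices without a declared scale are
#'   assumed uint8 when all values exceed 1.
#' @export
imageScale <- function(img) {
  sc <- attr(img, "scale")
  if (!is.null(sc)) return(sc)
  if (max(img) > 1) "uint8" else "unit"
}

#' Exact affine scale conversions
#'
#' `asUnit()` divides by 255; `asUint8()` multiplies by 255 and rounds half
#' up (`floor(x * 255 + 0.5)`), the only place rounding happens in the
#' pipeline.
#'
#' @param img grayscale image matrix.
#' @return converted image with the matching scale attribute.
#' @export
asUnit <- function(img) {
  if (imageScale(img) == "unit") return(grayImage(img, "unit"))
  grayImage(img / 255, "unit")
}

#' @rdname asUnit
#' @export
asUint8 <- function(img) {
  if (imageScale(img) == "uint8") return(grayImage(img, "uint8"))
  grayImage(floor(img * 255 + 0.5), "uint8")
}

## Shift matrix content by (dr, dc): out[r, c] = M[r - dr, c - dc],
## vacated cells take `fill`. The workhorse behind all morphology.
shiftMatrix <- function(M, dr, dc, fill) {
  nr <- nrow(M); nc <- ncol(M)
  out <- matrix(fill, nr, nc)
  if (dr >= nr || dr <= -nr || dc >= nc || dc <= -nc) return(out)
  rs <- max(1L, 1L + dr):min(nr, nr + dr)
  cs <- max(1L, 1L + dc):min(nc, nc + dc)
  out[rs, cs] <- M[rs - dr, cs - dc]
  out
}

## Evaluate `expr` under a fixed RNG seed without disturbing the caller's
## random-number stream.
withSeed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  expr
}

## Pad ranges defensively; used by validity checks.
stopifnotShape <- function(a, b, what = "masks") {
  if (!all(dim(a)[1:2] == dim(b)[1:2]))
    stop(what, " must share the same height and width")
  invisible(TRUE)
}
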