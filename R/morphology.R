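# Flat grayscale / binary morphology by shift-and-combine over the
# structuring-element offsets. Border policy: identity padding — cells
# outside the image behave as the neutral element (+Inf for erosion's
# minimum, -Inf / background for dilation's maximum), so borders act as if
# the image continued with non-constraining values. Structuring elements
# are centred and symmetric (odd sizes), so the complement duality, the
# adjunction behind opening/closing, and the set definition of dilation
# all hold with one and the same element.

dilateNumeric <- function(M, se, fill) {
  offs <- seOffsets(se)
  out <- matrix(fill, nrow(M), ncol(M))
  for (i in seq_len(nrow(offs)))
    out <- pmax(out, shiftMatrix(M, offs[i, 1], offs[i, 2], fill))
  out
}

erodeNumeric <- function(M, se, fill) {
  offs <- seOffsets(se)
  out <- matrix(fill, nrow(M), ncol(M))
  # minimum over the reflected footprint (same shift direction as dilation),
  # so erode(A) == !dilate(!A) holds with one and the same element
  for (i in seq_len(nrow(offs)))
    out <- pmin(out, shiftMatrix(M, offs[i, 1], offs[i, 2], fill))
  out
}

isBinaryMask <- function(M) is.matrix(M) && all(M %in% c(0L, 1L))

#' Morphological dilation
#'
#' Binary dilation follows the set definition `A + B = {z : (B^)_z
#' intersects A}` (reflection of the structuring element about its origin);
#' grayscale dilation is the windowed maximum over the reflected footprint.
#' Out-of-bounds neighbors are background (-Inf for grayscale).
#'
#' @param img binary \{0,1\} mask or grayscale image matrix.
#' @param se a [StructuringElement-class].
#' @return same type as the input.
#' @export
morphoDilate <- function(img, se) {
  if (isBinaryMask(img)) {
    out <- dilateNumeric(matrix(as.numeric(img), nrow(img)), se, 0)
    matrix(as.integer(out), nrow(img))
  } else {
    sc <- imageScale(img)
    grayImage(dilateNumeric(img, se, -Inf), sc)
  }
}

#' Morphological erosion
#'
#' Grayscale erosion is the windowed minimum over the footprint; binary
#' erosion is its \{0,1\} restriction and satisfies the complement duality
#' `erode(A) = !dilate(!A)`. Out-of-bounds neighbors are +Inf (binary: 1),
#' i.e. non-constraining.
#'
#' @inheritParams morphoDilate
#' @return same type as the input.
#' @export
morphoErode <- function(img, se) {
  if (isBinaryMask(img)) {
    out <- erodeNumeric(matrix(as.numeric(img), nrow(img)), se, 1)
    matrix(as.integer(out), nrow(img))
  } else {
    sc <- imageScale(img)
    grayImage(erodeNumeric(img, se, Inf), sc)
  }
}

#' Morphological opening and closing
#'
#' Opening is erosion followed by dilation with the same element
#' (anti-extensive, idempotent: removes bright structures the element does
#' not fit inside); closing is the dual dilation-then-erosion.
#'
#' @inheritParams morphoDilate
#' @return same type as the input.
#' @export
morphoOpen <- function(img, se) morphoDilate(morphoErode(img, se), se)

#' @rdname morphoOpen
#' @export
morphoClose <- function(img, se) morphoErode(morphoDilate(img, se), se)

#' White and black top-hat transforms
#'
#' `whiteTopHatTransform(f) = f - opening(f)` keeps bright structures
#' smaller than the structuring element (for vessel extraction it is
#' applied to the inverted green channel, so vessels are the bright
#' features while the slowly varying background and the optic disc are
#' suppressed). `blackTopHatTransform(f) = closing(f) - f` keeps dark
#' structures and equals the white top-hat of the inverted image. Both are
#' non-negative pixelwise.
#'
#' @inheritParams morphoDilate
#' @return grayscale image, same scale as the input.
#' @export
whiteTopHatTransform <- function(img, se) {
  opened <- morphoOpen(img, se)
  grayImage(img - opened, imageScale(img))
}

#' @rdname whiteTopHatTransform
#' @export
blackTopHatTransform <- function(img, se) {
  closed <- morphoClose(img, se)
  grayImage(closed - img, imageScale(img))
}
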