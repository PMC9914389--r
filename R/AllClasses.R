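#' @import methods
NULL

#' Structuring element for morphological operators
#'
#' A flat structuring element: a logical footprint matrix plus the origin
#' cell (1-based row/col inside the footprint). Disks of odd diameter d
#' contain the offsets with squared radius at most ((d-1)/2)^2; squares are
#' full s-by-s blocks.
#'
#' @slot footprint logical matrix, at least one `TRUE` cell.
#' @slot origin integer length-2 (row, col) inside the footprint.
#' @slot shape `"disk"`, `"square"` or `"custom"`.
#' @slot size integer diameter / side length (0 for custom footprints).
#' @export
setClass("StructuringElement",
  representation(footprint = "matrix", origin = "integer",
                 shape = "character", size = "integer"),
  validity = function(object) {
    fp <- object@footprint
    if (!is.logical(fp) || !any(fp)) return("footprint must contain TRUE cells")
    o <- object@origin
    if (length(o) != 2L || any(o < 1L) || o[1] > nrow(fp) || o[2] > ncol(fp))
      return("origin must index a cell of the footprint")
    TRUE
  })

#' Create a structuring element
#'
#' @param shape `"disk"` (odd diameter, offsets with dr^2+dc^2 <= r^2,
#'   r = (size-1)/2) or `"square"` (size-by-size block).
#' @param size positive odd integer, so the footprint is symmetric about
#'   its origin (asymmetric elements would break the erosion/dilation
#'   complement duality that the binary operators guarantee).
#' @return a [StructuringElement-class] with centred origin.
#' @examples
#' structuringElement("disk", 3)   # the 4-connected cross
#' structuringElement("square", 7)
#' @export
structuringElement <- function(shape = c("disk", "square"), size) {
  shape <- match.arg(shape)
  size <- as.integer(size)
  if (size < 1L || size %% 2L == 0L)
    stop("'size' must be a positive odd integer")
  if (shape == "disk") {
    r <- (size - 1L) / 2
    d <- outer((-r):r, (-r):r, function(a, b) a^2 + b^2)
    fp <- d <= r^2
  } else {
    fp <- matrix(TRUE, size, size)
  }
  new("StructuringElement", footprint = fp,
      origin = as.integer(c((nrow(fp) + 1L) %/% 2L, (ncol(fp) + 1L) %/% 2L)),
      shape = shape, size = size)
}

## Offsets (dr, dc) of TRUE cells relative to the origin, as an n x 2 matrix.
seOffsets <- function(se) {
  w <- which(se@footprint, arr.ind = TRUE)
  cbind(w[, 1] - se@origin[1], w[, 2] - se@origin[2])
}

#' Brightness-enhancement result
#'
#' Output of [enhanceBrightness()]: the remapped image together with the
#' selected averaging threshold tau, the value of the entropy-weighted
#' brightness objective at tau, and the image means before/after.
#'
#' @slot enhanced uint8 grayscale image matrix.
#' @slot tauStar selected averaging threshold (NA for degenerate input).
#' @slot objectiveValue objective (relative mean gain times entropy) at tauStar.
#' @slot entropy Shannon entropy (bits) of the enhanced image's histogram.
#' @slot meanBefore,meanAfter image means on the uint8 scale.
#' @slot degenerate TRUE when the input histogram was a point mass and the
#'   image was returned unchanged.
#' @export
setClass("EnhancementResult",
  representation(enhanced = "matrix", tauStar = "numeric",
                 objectiveValue = "numeric", entropy = "numeric",
                 meanBefore = "numeric", meanAfter = "numeric",
                 degenerate = "logical"),
  validity = function(object) {
    if (!object@degenerate &&
        (is.na(object@tauStar) || object@tauStar <= 0 || object@tauStar >= 1))
      return("tauStar must lie strictly inside (0, 1)")
    TRUE
  })

#' Fuzzy clustering state
#'
#' The converged (or iteration-capped) state of fuzzy c-means or of the
#' Gaussian-kernel weighted variant: centroids, the c-by-N membership
#' matrix, and the per-iteration objective trace.
#'
#' @slot centroids c-by-D matrix of cluster centres.
#' @slot memberships c-by-N matrix; every column sums to 1.
#' @slot objectiveTrace objective value after each iteration.
#' @slot colsumDev max absolute deviation of membership column sums from 1,
#'   recorded after each iteration.
#' @slot iterationsRun number of update iterations executed.
#' @slot converged TRUE when the membership change dropped below `tol`.
#' @slot deltaFinal last max-abs membership change.
#' @slot method `"fcm"` or `"wkfcm"`.
#' @export
setClass("FuzzyState",
  representation(centroids = "matrix", memberships = "matrix",
                 objectiveTrace = "numeric", colsumDev = "numeric",
                 iterationsRun = "integer", converged = "logical",
                 deltaFinal = "numeric", method = "character"),
  validity = function(object) {
    U <- object@memberships
    if (any(U < -1e-9) || any(U > 1 + 1e-9))
      return("memberships must lie in [0, 1]")
    if (max(abs(colSums(U) - 1)) > 1e-9)
      return("membership columns must sum to 1 (1e-9)")
    if (nrow(object@centroids) != nrow(U))
      return("centroids and memberships disagree on cluster count")
    if (any(!is.finite(object@objectiveTrace)))
      return("objective trace must be finite")
    TRUE
  })

#' Pixel-based confusion counts
#'
#' Vessel is the positive class: tp = vessel pixels extracted as vessel,
#' fn = vessel pixels missed, tn/fp analogously for background.
#'
#' @slot tp,tn,fp,fn non-negative integer counts.
#' @export
setClass("ConfusionCounts",
  representation(tp = "integer", tn = "integer", fp = "integer", fn = "integer"),
  validity = function(object) {
    v <- c(object@tp, object@tn, object@fp, object@fn)
    if (any(v < 0L)) return("counts must be non-negative")
    TRUE
  })

#' End-to-end segmentation result
#'
#' @slot mask final binary vessel mask (after dilation-based refinement).
#' @slot maskPreDbf binary mask straight after intensity thresholding.
#' @slot clusterState the [FuzzyState-class] of the clustering stage.
#' @slot mapc mapping coefficient vs ground truth (NA when no truth given).
#' @slot metrics named list (sen/spec/acc percent + counts), empty without
#'   ground truth.
#' @slot stages named list of intermediate images (kept when requested).
#' @export
setClass("SegmentationResult",
  representation(mask = "matrix", maskPreDbf = "matrix",
                 clusterState = "FuzzyState", mapc = "numeric",
                 metrics = "list", stages = "list"),
  validity = function(object) {
    if (!all(object@mask %in% c(0L, 1L)) ||
        !all(object@maskPreDbf %in% c(0L, 1L)))
      return("masks must be two-valued {0,1}")
    if (any(object@mask < object@maskPreDbf))
      return("final mask must contain the pre-refinement mask (extensivity)")
    if (!is.na(object@mapc) && (object@mapc < 0 || object@mapc > 0.5))
      return("mapc must lie in [0, 0.5]")
    TRUE
  })

#' Synthetic fundus phantom specification
#'
#' Parameters of the phantom generator; see [generatePhantom()] for what
#' each feature emulates. All intensities are on the unit scale.
#'
#' @slot height,width image size in pixels.
#' @slot nSeedVessels number of primary vessels leaving the optic disc.
#' @slot branchProb per-step probability that a vessel spawns a branch.
#' @slot widthRange integer (min, max) vessel diameter in pixels.
#' @slot vesselContrast green-channel intensity drop of vessel pixels.
#' @slot vignetteStrength peripheral brightness loss of the background.
#' @slot odRadius,odBrightness optic-disc radius (px) and brightness gain.
#' @slot noiseSd Gaussian noise standard deviation (unit scale).
#' @slot saltPepperFrac fraction of pixels hit by impulse noise.
#' @slot seed RNG seed (mandatory; the phantom is a pure function of it).
#' @export
setClass("PhantomSpec",
  representation(height = "integer", width = "integer",
                 nSeedVessels = "integer", branchProb = "numeric",
                 widthRange = "integer", vesselContrast = "numeric",
                 vignetteStrength = "numeric", odRadius = "numeric",
                 odBrightness = "numeric", noiseSd = "numeric",
                 saltPepperFrac = "numeric", seed = "integer"),
  validity = function(object) {
    if (object@height < 64L || object@width < 64L)
      return("phantom must be at least 64x64")
    if (object@nSeedVessels < 1L) return("need at least one seed vessel")
    if (object@vesselContrast <= 0) return("vesselContrast must be positive")
    if (length(object@widthRange) != 2L || object@widthRange[1] < 1L ||
        object@widthRange[2] < object@widthRange[1])
      return("widthRange must be increasing positive integers")
    if (object@branchProb < 0 || object@branchProb > 1)
      return("branchProb must lie in [0, 1]")
    if (is.na(object@seed)) return("seed is mandatory")
    TRUE
  })

#' Generated retinal phantom
#'
#' @slot image H-by-W-by-3 uint8 RGB array.
#' @slot gt binary ground-truth vessel mask (exact, by construction).
#' @slot fov binary field-of-view mask.
#' @slot spec the generating [PhantomSpec-class].
#' @export
setClass("RetinalPhantom",
  representation(image = "array", gt = "matrix", fov = "matrix",
                 spec = "PhantomSpec"),
  validity = function(object) {
    if (length(dim(object@image)) != 3L || dim(object@image)[3] != 3L)
      return("image must be H x W x 3")
    if (!all(object@gt %in% c(0L, 1L)) || !all(object@fov %in% c(0L, 1L)))
      return("gt and fov must be binary")
    if (any(object@gt > object@fov))
      return("ground truth must lie inside the field of view")
    TRUE
  })
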