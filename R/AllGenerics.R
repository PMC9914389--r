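#' Accessors for fuzzy clustering state and results
#'
#' `centroids()`, `memberships()`, `objectiveTrace()`, `convergedState()`
#' read the corresponding slots of a [FuzzyState-class];
#' `vesselMask()` and `mapCoefficient()` read a [SegmentationResult-class].
#'
#' @param object a fitted object.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("centroids", function(object) standardGeneric("centroids"))

#' @rdname accessors
#' @export
setGeneric("memberships", function(object) standardGeneric("memberships"))

#' @rdname accessors
#' @export
setGeneric("objectiveTrace", function(object) standardGeneric("objectiveTrace"))

#' @rdname accessors
#' @export
setGeneric("convergedState", function(object) standardGeneric("convergedState"))

#' @rdname accessors
#' @export
setGeneric("vesselMask", function(object) standardGeneric("vesselMask"))

#' @rdname accessors
#' @export
setGeneric("mapCoefficient", function(object) standardGeneric("mapCoefficient"))

#' @rdname accessors
#' @export
setMethod("centroids", "FuzzyState", function(object) object@centroids)

#' @rdname accessors
#' @export
setMethod("memberships", "FuzzyState", function(object) object@memberships)

#' @rdname accessors
#' @export
setMethod("objectiveTrace", "FuzzyState", function(object) object@objectiveTrace)

#' @rdname accessors
#' @export
setMethod("convergedState", "FuzzyState", function(object) object@converged)

#' @rdname accessors
#' @export
setMethod("vesselMask", "SegmentationResult", function(object) object@mask)

#' @rdname accessors
#' @export
setMethod("mapCoefficient", "SegmentationResult", function(object) object@mapc)

setMethod("show", "StructuringElement", function(object) {
  cat(sprintf("StructuringElement: %s, size %d (%d active cells)\n",
              object@shape, object@size, sum(object@footprint)))
})

setMethod("show", "FuzzyState", function(object) {
  cat(sprintf("FuzzyState (%s): %d clusters, %d points\n", object@method,
              nrow(object@memberships), ncol(object@memberships)))
  cat(sprintf("  iterations: %d  converged: %s  final delta: %.3g\n",
              object@iterationsRun, object@converged, object@deltaFinal))
  cat("  centroids:", paste(signif(object@centroids, 5), collapse = ", "), "\n")
})

setMethod("show", "EnhancementResult", function(object) {
  if (object@degenerate) {
    cat("EnhancementResult: degenerate (constant image), unchanged\n")
  } else {
    cat(sprintf(
      "EnhancementResult: tau* = %.2f, objective = %.4f, H = %.3f bits\n",
      object@tauStar, object@objectiveValue, object@entropy))
    cat(sprintf("  mean brightness %.2f -> %.2f\n",
                object@meanBefore, object@meanAfter))
  }
})

setMethod("show", "ConfusionCounts", function(object) {
  cat(sprintf("ConfusionCounts: TP %d  FN %d  TN %d  FP %d\n",
              object@tp, object@fn, object@tn, object@fp))
})

setMethod("show", "SegmentationResult", function(object) {
  cat(sprintf("SegmentationResult: %d x %d, %d vessel pixels (%d pre-DBF)\n",
              nrow(object@mask), ncol(object@mask),
              sum(object@mask), sum(object@maskPreDbf)))
  if (!is.na(object@mapc)) cat(sprintf("  MAPC: %.4f\n", object@mapc))
  if (length(object@metrics))
    cat(sprintf("  SEN %.2f  SPEC %.2f  ACC %.2f\n", object@metrics$sen,
                object@metrics$spec, object@metrics$acc))
})

setMethod("show", "RetinalPhantom", function(object) {
  cat(sprintf("RetinalPhantom %d x %d (seed %d): %d vessel px, %.1f%% of FOV\n",
              object@spec@height, object@spec@width, object@spec@seed,
              sum(object@gt), 100 * sum(object@gt) / sum(object@fov)))
})
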