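# End-to-end extractor: green channel -> brightness normalization ->
# median denoising -> inversion -> white top-hat -> WKFCM clustering of
# the top-hat intensities -> vessel-membership image -> intensity
# thresholding at 128 -> dilation-based refinement (DBF).

#' Pipeline configuration
#'
#' Nested configuration for every stage, carrying the method's constants
#' as defaults: tau grid step 0.01, 3 x 3 median window, disk-15 top-hat
#' element, inversion before the white top-hat (vessels are dark in the
#' green channel; the top-hat extracts bright features), c = 2, m = 3,
#' sigma = 0.5, 150 iterations, binary threshold 128, and a 3 x 3 square
#' refinement element — the 8-neighborhood of each pixel, matching the
#' refinement's description as examining the connectivity between a pixel
#' and every one of its surrounding neighbors, and keeping the mask halo
#' to 1 px so specificity survives (disk/square 5 or 7 are one config key
#' away).
#'
#' @param preprocess list: `enhance`, `denoise` (logicals),
#'   `tau_grid_step`, `median_window`.
#' @param morphology list: `wth_se` (`shape`, `size`), `dbf_se`,
#'   `invert_before_wth`.
#' @param cluster a [fuzzyConfig()].
#' @param threshold binary threshold on the uint8 membership image
#'   (default 128, i.e. membership 0.5).
#' @param vessel_rule which centroid is the vessel cluster:
#'   `"brighter_centroid"` (default; vessels are the bright top-hat
#'   features) or `"darker_centroid"`.
#' @param threshold_wth threshold the top-hat image directly instead of
#'   the clustered membership image (comparison mode, default FALSE).
#' @param use_fov restrict metrics to the FOV mask when one is supplied.
#' @return nested list of class `pipelineConfig`.
#' @export
pipelineConfig <- function(preprocess = list(), morphology = list(),
                           cluster = fuzzyConfig(), threshold = 128L,
                           vessel_rule = c("brighter_centroid",
                                           "darker_centroid"),
                           threshold_wth = FALSE, use_fov = FALSE) {
  pp <- utils::modifyList(
    list(enhance = TRUE, denoise = TRUE, tau_grid_step = 0.01,
         median_window = 3L), preprocess)
  mo <- utils::modifyList(
    list(wth_se = list(shape = "disk", size = 15L),
         dbf_se = list(shape = "square", size = 3L),
         invert_before_wth = TRUE), morphology)
  threshold <- as.integer(threshold)
  if (threshold < 0L || threshold > 255L)
    stop("'threshold' must lie in [0, 255]")
  structure(list(preprocess = pp, morphology = mo, cluster = cluster,
                 threshold = threshold, vessel_rule = match.arg(vessel_rule),
                 threshold_wth = isTRUE(threshold_wth),
                 use_fov = isTRUE(use_fov)),
            class = "pipelineConfig")
}

#' Read a pipeline configuration from a YAML file
#'
#' The file mirrors the [pipelineConfig()] structure; absent keys keep
#' their defaults. The legacy termination constant `T` under `cluster` is
#' accepted and recorded but non-operative (see [fuzzyConfig()]).
#'
#' @param path YAML file path.
#' @return a `pipelineConfig`.
#' @export
readPipelineConfig <- function(path) {
  y <- yaml::read_yaml(path)
  cl <- do.call(fuzzyConfig, y$cluster %||% list())
  pipelineConfig(preprocess = y$preprocess %||% list(),
                 morphology = y$morphology %||% list(),
                 cluster = cl,
                 threshold = y$threshold %||% 128L,
                 vessel_rule = y$vessel_rule %||% "brighter_centroid",
                 threshold_wth = y$threshold_wth %||% FALSE,
                 use_fov = y$use_fov %||% FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Render cluster memberships back onto the pixel grid
#'
#' Takes the vessel cluster's membership row, reshapes it to the image,
#' and maps \[0, 1\] affinely onto uint8 (round half up), ready for
#' intensity thresholding: membership 0.5 becomes 128.
#'
#' @param state a [FuzzyState-class] clustered from column-major pixels.
#' @param vesselCluster row index of the vessel cluster.
#' @param shape integer (rows, cols); `prod(shape)` must equal the point
#'   count.
#' @return uint8 grayscale membership image.
#' @export
membershipImage <- function(state, vesselCluster, shape) {
  U <- memberships(state)
  if (prod(shape) != ncol(U))
    stop("shape ", shape[1], "x", shape[2],
         " inconsistent with ", ncol(U), " clustered pixels")
  asUint8(grayImage(matrix(U[vesselCluster, ], shape[1], shape[2]), "unit"))
}

#' Binary intensity thresholding
#'
#' Pixel >= t becomes vessel (1), below becomes background (0); the
#' default t = 128 is the optimal histogram-splitting value, with the
#' boundary inclusive (128 is vessel, 127 background).
#'
#' @param img uint8 grayscale image.
#' @param t integer threshold in \[0, 255\].
#' @return binary \{0,1\} mask.
#' @export
thresholdBinary <- function(img, t = 128L) {
  if (imageScale(img) != "uint8") stop("thresholdBinary() needs a uint8 image")
  t <- as.integer(t)
  if (t < 0L || t > 255L) stop("'t' must lie in [0, 255]")
  matrix(as.integer(img >= t), nrow(img), ncol(img))
}

#' Dilation-based refinement (DBF)
#'
#' Dilates the thresholded mask, reconnecting fragmented micro-vessel
#' pixels and filling small holes; the output always contains the input
#' (extensive), so false negatives can only decrease.
#'
#' @param mask binary \{0,1\} mask.
#' @param se a [StructuringElement-class] (pipeline default: the 3 x 3
#'   square, i.e. each pixel's 8-neighborhood).
#' @return binary \{0,1\} mask containing `mask`.
#' @export
applyDBF <- function(mask, se = structuringElement("square", 3L)) {
  morphoDilate(mask, se)
}

seFromConfig <- function(cfg) structuringElement(cfg$shape, cfg$size)

#' Extract retinal vessels end to end
#'
#' Runs the full unsupervised extractor on an RGB fundus-style image:
#' green-channel selection, optional brightness normalization and median
#' denoising, inversion, white top-hat, WKFCM clustering of the top-hat
#' intensities (1-D pixel features), vessel-membership thresholding at
#' 128, and dilation-based refinement. The result is a pure function of
#' (image, config, seed).
#'
#' @param img H x W x 3 uint8 RGB array (see [readFundusImage()]).
#' @param config a [pipelineConfig()].
#' @param gt optional binary ground-truth mask; when given, the mapping
#'   coefficient and sensitivity/specificity/accuracy are filled in.
#' @param fov optional binary FOV mask (used for metrics when
#'   `config$use_fov` is TRUE).
#' @param keepStages keep intermediate images in the result (default
#'   FALSE).
#' @return a [SegmentationResult-class].
#' @export
segmentVessels <- function(img, config = pipelineConfig(), gt = NULL,
                           fov = NULL, keepStages = FALSE) {
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "': ", conditionMessage(e), call. = FALSE))
  }
  ch <- stage("split_channels", splitChannels(img))
  g <- ch$green
  if (isTRUE(config$preprocess$enhance)) {
    grid <- seq(config$preprocess$tau_grid_step, 0.99,
                by = config$preprocess$tau_grid_step)
    enh <- stage("enhance_brightness", enhanceBrightness(g, grid))
    g <- enh@enhanced
  } else enh <- NULL
  if (isTRUE(config$preprocess$denoise))
    g <- stage("median_denoise",
               medianDenoise(g, config$preprocess$median_window))
  gU <- asUnit(g)
  work <- if (isTRUE(config$morphology$invert_before_wth))
    grayImage(1 - gU, "unit") else gU
  wth <- stage("white_tophat",
               whiteTopHatTransform(work, seFromConfig(config$morphology$wth_se)))
  if (isTRUE(config$threshold_wth)) {
    mi <- asUint8(grayImage(matrix(normalizeHypercube(as.vector(wth)),
                                   nrow(wth), ncol(wth)), "unit"))
    state <- new("FuzzyState", centroids = matrix(0, 2, 1),
                 memberships = matrix(0.5, 2, length(wth)),
                 objectiveTrace = numeric(0), colsumDev = numeric(0),
                 iterationsRun = 0L, converged = TRUE, deltaFinal = 0,
                 method = "wkfcm")
  } else {
    state <- stage("run_wkfcm",
                   runWKFCM(as.vector(wth), config$cluster, normalize = TRUE))
    vi <- if (config$vessel_rule == "brighter_centroid")
      which.max(centroids(state)[, 1]) else which.min(centroids(state)[, 1])
    mi <- stage("membership_image",
                membershipImage(state, vi, dim(wth)))
  }
  maskPre <- stage("threshold_binary", thresholdBinary(mi, config$threshold))
  # thresholding is restricted to the field of view whenever a FOV mask is
  # supplied: the black surround carries no information and its rim is a
  # known top-hat artifact
  if (!is.null(fov)) maskPre <- maskPre * fov
  mask <- stage("apply_dbf",
                applyDBF(maskPre, seFromConfig(config$morphology$dbf_se)))
  if (!is.null(fov)) mask <- mask * fov
  mapc <- NA_real_; metr <- list()
  if (!is.null(gt)) {
    mfov <- if (isTRUE(config$use_fov)) fov else NULL
    mapc <- mapCoefficientMasks(gt, mask)
    metr <- segMetrics(confusionCounts(gt, mask, mfov))
    metr$counts_pre_dbf <- segMetrics(confusionCounts(gt, maskPre, mfov))
  }
  stages <- if (keepStages)
    list(green = ch$green, enhanced = enh, denoised = g, tophat = wth,
         membership = mi) else list()
  new("SegmentationResult", mask = mask, maskPreDbf = maskPre,
      clusterState = state, mapc = mapc, metrics = metr, stages = stages)
}

#' Sweep the clustering parameter grids
#'
#' Runs [segmentVessels()] over the cartesian product of fuzzifier, kernel
#' width, cluster count and seed, returning one row of metrics per
#' combination. The fuzzifier grid may include 1 (the original sweep
#' does): m = 1 has an undefined membership exponent and is skipped with a
#' warning. c = 1 is degenerate and skipped likewise.
#'
#' @param img RGB image array.
#' @param gt binary ground-truth mask.
#' @param mList,sigmaList,cList,seeds parameter grids; defaults are the
#'   method's published sweep (m in 1,2,3,5,7,9,11,12,13; sigma in
#'   0.3, 0.5, 0.7; c in 1..5).
#' @param config base [pipelineConfig()] supplying everything else.
#' @return data.frame with columns m, sigma, c, seed, sen, spec, acc,
#'   mapc.
#' @export
sweepParameters <- function(img, gt,
                            mList = c(1, 2, 3, 5, 7, 9, 11, 12, 13),
                            sigmaList = c(0.3, 0.5, 0.7),
                            cList = 1:5, seeds = 1L,
                            config = pipelineConfig()) {
  if (any(mList == 1)) {
    warning("m = 1 makes the membership exponent undefined; skipped")
    mList <- mList[mList != 1]
  }
  if (any(cList < 2)) {
    warning("c = 1 is degenerate; skipped")
    cList <- cList[cList >= 2]
  }
  grid <- expand.grid(m = mList, sigma = sigmaList, c = cList, seed = seeds)
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    cl <- fuzzyConfig(c = grid$c[i], m = grid$m[i], sigma = grid$sigma[i],
                      maxIter = config$cluster$maxIter,
                      tol = config$cluster$tol, seed = grid$seed[i])
    cfg <- config; cfg$cluster <- cl
    res <- segmentVessels(img, cfg, gt = gt)
    data.frame(m = grid$m[i], sigma = grid$sigma[i], c = grid$c[i],
               seed = grid$seed[i], sen = res@metrics$sen,
               spec = res@metrics$spec, acc = res@metrics$acc,
               mapc = res@mapc)
  })
  do.call(rbind, rows)
}
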