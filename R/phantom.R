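# Synthetic fundus phantom with exact vessel ground truth. The generator
# emulates the imaging conditions the extractor is built against: a dark
# circular field of view on a black surround, a vignetted (non-uniform)
# background, a bright optic-disc blob, a branching vessel tree of mixed
# widths darker than background predominantly in the green channel, and
# Gaussian plus salt-and-pepper noise. The ground-truth mask marks exactly
# the rendered vessel pixels (no anti-aliasing), so pixel-based metrics
# against it are exact.

#' Specify a synthetic fundus phantom
#'
#' Defaults describe a moderately sparse vasculature on a 256 x 256 frame:
#' six primary vessels leaving the optic disc, occasional branching,
#' diameters tapering from up to 8 px down to 1 px (so both large and
#' micro vessels occur in every phantom), a green-channel contrast drop of
#' 0.22, mild vignetting, and light mixed noise. Within-FOV vessel density
#' lands in the low single-digit percent range typical of moderately
#' sparse fundus fields.
#'
#' @param height,width frame size in pixels (default 256 x 256).
#' @param nSeedVessels primary vessels leaving the optic disc (default 6).
#' @param branchProb per-step branching probability (default 0.035).
#' @param widthRange integer (min, max) vessel diameter in px, default
#'   (1, 8).
#' @param vesselContrast green-channel intensity drop at vessel pixels
#'   (unit scale, default 0.22).
#' @param vignetteStrength peripheral brightness loss (default 0.5, strong
#'   enough that peripheral background reaches vessel-like intensities —
#'   the condition the brightness normalization exists to correct).
#' @param odRadius,odBrightness optic-disc radius in px (default 16) and
#'   brightness gain (default 0.25).
#' @param noiseSd Gaussian noise sd on the unit scale (default 0.01,
#'   about 2.5 gray levels — typical fundus sensor noise).
#' @param saltPepperFrac fraction of in-FOV pixels hit by impulse noise
#'   (default 0.004).
#' @param seed RNG seed; the phantom is a deterministic function of the
#'   spec including the seed.
#' @return a [PhantomSpec-class].
#' @export
phantomSpec <- function(height = 256L, width = 256L, nSeedVessels = 6L,
                        branchProb = 0.035, widthRange = c(1L, 8L),
                        vesselContrast = 0.22, vignetteStrength = 0.5,
                        odRadius = 16, odBrightness = 0.25, noiseSd = 0.01,
                        saltPepperFrac = 0.004, seed = 1L) {
  new("PhantomSpec", height = as.integer(height), width = as.integer(width),
      nSeedVessels = as.integer(nSeedVessels), branchProb = branchProb,
      widthRange = as.integer(widthRange), vesselContrast = vesselContrast,
      vignetteStrength = vignetteStrength, odRadius = odRadius,
      odBrightness = odBrightness, noiseSd = noiseSd,
      saltPepperFrac = saltPepperFrac, seed = as.integer(seed))
}

## Stamp a disk of diameter w (the vessel width) onto the contrast-profile
## canvas at continuous position (r, c). The profile is 1 on the centerline
## and falls to 0.5 at the rim — the partial-volume cross-section real
## vessels show — and the ground truth is exactly the stamped support
## (profile > 0), so the mask itself is not anti-aliased.
stampDisk <- function(prof, r, c, w) {
  rad <- max(w / 2, 0.5)
  ir <- round(r); ic <- round(c)
  lo <- floor(-rad); hi <- ceiling(rad)
  rr <- (ir + lo):(ir + hi); cc <- (ic + lo):(ic + hi)
  rr <- rr[rr >= 1 & rr <= nrow(prof)]
  cc <- cc[cc >= 1 & cc <= ncol(prof)]
  if (!length(rr) || !length(cc)) return(prof)
  d2 <- outer((rr - ir)^2, (cc - ic)^2, "+")
  p <- ifelse(d2 <= rad^2, 1 - 0.3 * d2 / rad^2, 0)
  prof[rr, cc] <- pmax(prof[rr, cc], p)
  prof
}

## Trace one vessel branch as a random walk; returns the updated gt canvas
## and (possibly) enqueues branch points.
traceBranch <- function(gt, fovR, center, r, c, theta, width, nSteps,
                        branchProb, queue) {
  hairline <- 0L
  for (s in seq_len(nSteps)) {
    w <- max(1, width * (1 - 0.5 * s / nSteps))   # taper toward the tip
    # once a vessel thins to the 1 px resolution limit it fades out after a
    # short visible run rather than persisting as a long hairline
    if (w <= 1.2) {
      hairline <- hairline + 1L
      if (hairline > 10L) break
    }
    gt <- stampDisk(gt, r, c, w)
    theta <- theta + stats::rnorm(1, 0, 0.12)
    r <- r + sin(theta); c <- c + cos(theta)
    if ((r - center[1])^2 + (c - center[2])^2 > (0.98 * fovR)^2) break
    if (w > 1.5 && stats::runif(1) < branchProb) {
      queue[[length(queue) + 1L]] <- list(
        r = r, c = c, theta = theta + sample(c(-1, 1), 1) * stats::runif(1, 0.5, 0.9),
        width = max(1, w - 1), nSteps = ceiling(nSteps * 0.5))
    }
  }
  list(gt = gt, queue = queue)
}

## Smooth random field in [-amp, amp]: coarse Gaussian grid, bilinearly
## interpolated to H x W. Emulates the large-scale choroidal mottling of
## real fundus backgrounds (smooth enough to be invisible to the top-hat).
smoothField <- function(H, W, nodes = 7L, amp = 0.1) {
  coarse <- matrix(stats::rnorm((nodes + 1L)^2, 0, 1), nodes + 1L)
  rowIdx <- seq(1, nodes + 1L, length.out = H)
  colIdx <- seq(1, nodes + 1L, length.out = W)
  byRow <- apply(coarse, 2L, function(colv)
    stats::approx(seq_len(nodes + 1L), colv, rowIdx)$y)
  field <- t(apply(byRow, 1L, function(rowv)
    stats::approx(seq_len(nodes + 1L), rowv, colIdx)$y))
  amp * field / max(abs(field))
}

#' Generate a synthetic fundus phantom
#'
#' Renders, in order: circular FOV on black; radial vignette; optic-disc
#' blob; a branching vessel tree by seeded random walks (ground truth is
#' exactly the stamped pixels, clipped to the FOV); then channel-specific
#' vessel darkening (green strongest), Gaussian noise, and salt-and-pepper
#' impulses. Bit-for-bit reproducible per seed.
#'
#' @param spec a [PhantomSpec-class].
#' @return a [RetinalPhantom-class] (uint8 RGB image, binary gt and fov).
#' @export
generatePhantom <- function(spec = phantomSpec()) {
  H <- spec@height; W <- spec@width
  if (spec@vesselContrast <= 0) stop("degenerate spec: zero vessel contrast")
  withSeed(spec@seed, {
    center <- c(H, W) / 2
    fovR <- 0.46 * min(H, W)
    rows <- matrix(seq_len(H), H, W)
    cols <- matrix(seq_len(W), H, W, byrow = TRUE)
    d <- sqrt((rows - center[1])^2 + (cols - center[2])^2)
    fov <- matrix(as.integer(d <= fovR), H, W)

    # vignetted background (green) with smooth choroidal mottling; red
    # brighter, blue darker, as in fundus
    vig <- 1 - spec@vignetteStrength * (d / fovR)^2
    tex <- smoothField(H, W)
    green <- (0.55 + tex) * vig
    # optic disc: bright blob offset from center
    odc <- center + c(0, 0.55 * fovR)
    dOD <- sqrt((rows - odc[1])^2 + (cols - odc[2])^2)
    green <- green + spec@odBrightness * exp(-(dOD / spec@odRadius)^2)

    # draw all noise ahead of the vessel tree so that the density governor
    # (which stops branch generation early on dense seeds) cannot perturb
    # the noise realization of the retained structure
    noiseArr <- if (spec@noiseSd > 0)
      array(stats::rnorm(H * W * 3L, 0, spec@noiseSd), c(H, W, 3L)) else NULL
    inFov <- which(fov == 1L)
    nImp <- round(spec@saltPepperFrac * length(inFov))
    impHit <- if (nImp > 0) sample(inFov, nImp) else integer(0)
    impVal <- stats::runif(nImp) < 0.5

    # vessel tree from the optic-disc rim
    gt <- matrix(0, H, W)            # contrast-profile canvas
    queue <- list()
    for (v in seq_len(spec@nSeedVessels)) {
      ang <- 2 * pi * (v - 0.5) / spec@nSeedVessels + stats::rnorm(1, 0, 0.25)
      r0 <- odc[1] + spec@odRadius * 0.6 * sin(ang)
      c0 <- odc[2] + spec@odRadius * 0.6 * cos(ang)
      w0 <- stats::runif(1, spec@widthRange[1] + 2, spec@widthRange[2])
      out <- traceBranch(gt, fovR, center, r0, c0, ang,
                         w0, nSteps = round(0.95 * fovR),
                         branchProb = spec@branchProb, queue = queue)
      gt <- out$gt; queue <- out$queue
    }
    # side branches, with a density governor: once the stamped tree reaches
    # 13% of the FOV no further branches are drawn, keeping the within-FOV
    # vessel density inside the 2-15% band typical of fundus fields
    fovArea <- sum(fov)
    while (length(queue)) {
      if (sum(gt > 0 & fov == 1L) / fovArea >= 0.13) break
      b <- queue[[1]]; queue <- queue[-1]
      out <- traceBranch(gt, fovR, center, b$r, b$c, b$theta, b$width,
                         b$nSteps, spec@branchProb, queue)
      gt <- out$gt; queue <- out$queue
    }
    prof <- gt * fov
    gtm <- matrix(as.integer(prof > 0), H, W)

    red <- (0.78 + tex) * vig; blue <- (0.16 + 0.5 * tex) * vig
    green <- green - spec@vesselContrast * prof
    red <- red - 0.35 * spec@vesselContrast * prof
    blue <- blue - 0.10 * spec@vesselContrast * prof

    img <- array(0, c(H, W, 3L))
    img[, , 1] <- red; img[, , 2] <- green; img[, , 3] <- blue
    # FOV cut, then noise inside the FOV
    for (k in 1:3) img[, , k] <- img[, , k] * fov
    if (!is.null(noiseArr)) img <- img + noiseArr * as.vector(fov)
    if (nImp > 0) {
      for (k in 1:3) {
        plane <- img[, , k]
        plane[impHit] <- ifelse(impVal, 1, 0)
        img[, , k] <- plane
      }
    }
    img <- pmin(pmax(img, 0), 1)
    img <- floor(img * 255 + 0.5)
    new("RetinalPhantom", image = img, gt = gtm, fov = fov, spec = spec)
  })
}
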