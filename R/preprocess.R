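# Brightness normalization by averaging-threshold optimization and median
# denoising. The normalization shifts histogram mass upward by a
# tau-controlled constant, imposes the shifted (renormalized) histogram on
# the image by monotone histogram specification, and picks the tau whose
# remap maximizes (relative mean-brightness gain) x (entropy of the
# remapped histogram).

#' Shift a histogram by the averaging threshold
#'
#' Adds `tau * max(h) / 2` to every bin of a 256-bin histogram, producing
#' the real-valued target histogram of the averaging-threshold enhancement.
#'
#' @param h integer histogram of length 256 (see [computeHistogram()]).
#' @param tau averaging threshold, strictly in (0, 1).
#' @return numeric vector of length 256.
#' @examples
#' h <- c(4, rep(0, 255))
#' shiftHistogram(h, 0.5)[1:3]  # 5 1 1
#' @export
shiftHistogram <- function(h, tau) {
  if (length(h) != 256L || any(h < 0)) stop("'h' must be a 256-bin histogram")
  if (!is.finite(tau) || tau <= 0 || tau >= 1)
    stop("'tau' must lie strictly in (0, 1)")
  h + tau * max(h) / 2
}

#' Shannon entropy of a discrete distribution, in bits
#'
#' @param p non-negative probability vector summing to 1 (within 1e-9);
#'   zero bins contribute 0 (the 0 log 0 convention).
#' @return entropy in bits (base-2 logarithm).
#' @examples
#' shannonEntropy(rep(1 / 256, 256))  # 8
#' shannonEntropy(c(0.5, 0.25, 0.25)) # 1.5
#' @export
shannonEntropy <- function(p) {
  if (any(p < 0)) stop("'p' must be non-negative")
  if (abs(sum(p) - 1) > 1e-9) stop("'p' must sum to 1 (within 1e-9)")
  nz <- p[p > 0]
  -sum(nz * log2(nz))
}

## Monotone histogram-specification lookup table mapping source values
## 0..255 onto the target pmf: LUT[v] = smallest u with CDFt(u) >= CDFo(v).
specificationLUT <- function(hSource, pTarget) {
  Co <- cumsum(hSource) / sum(hSource)
  Ct <- cumsum(pTarget)
  # count of target CDF entries strictly below Co gives the 0-based level
  lut <- findInterval(Co - 1e-12, Ct)
  pmin(lut, 255L)
}

#' Brightness enhancement by averaging-threshold optimization
#'
#' For each tau on the grid the 256-bin histogram is shifted
#' (`h + tau * max(h) / 2`), renormalized to a target distribution, and the
#' image is remapped onto it by monotone histogram specification. The
#' returned remap maximizes the objective
#' `((mean_after - mean_before) / mean_before) * H`, with `H` the Shannon
#' entropy (bits) of the remapped image's normalized histogram. Ties take
#' the lowest tau. The whole search runs on histograms alone (a 256-entry
#' lookup table per tau); the image is remapped once at the end.
#'
#' A constant image (point-mass histogram, entropy 0) is returned unchanged
#' with objective 0 and the `degenerate` flag set.
#'
#' @param img grayscale image, uint8 scale.
#' @param tauGrid candidate thresholds in (0, 1); default `seq(0.01, 0.99,
#'   by = 0.01)`.
#' @return an [EnhancementResult-class].
#' @export
enhanceBrightness <- function(img, tauGrid = seq(0.01, 0.99, by = 0.01)) {
  if (imageScale(img) != "uint8") stop("enhanceBrightness() needs a uint8 image")
  if (length(tauGrid) == 0L || any(tauGrid <= 0) || any(tauGrid >= 1))
    stop("'tauGrid' must be a non-empty subset of (0, 1)")
  h <- computeHistogram(img)
  N <- sum(h)
  meanBefore <- sum((0:255) * h) / N
  if (sum(h > 0) == 1L || meanBefore == 0) {
    return(new("EnhancementResult", enhanced = img, tauStar = NA_real_,
               objectiveValue = 0, entropy = 0, meanBefore = meanBefore,
               meanAfter = meanBefore, degenerate = TRUE))
  }
  best <- list(obj = -Inf)
  for (tau in sort(tauGrid)) {
    hBar <- shiftHistogram(h, tau)
    lut <- specificationLUT(h, hBar / sum(hBar))
    hEnh <- vapply(0:255, function(u) sum(h[lut == u]), numeric(1))
    meanAfter <- sum((0:255) * hEnh) / N
    H <- shannonEntropy(hEnh / N)
    obj <- (meanAfter - meanBefore) / meanBefore * H
    if (obj > best$obj + 1e-15) {
      best <- list(obj = obj, tau = tau, lut = lut, H = H,
                   meanAfter = meanAfter)
    }
  }
  enhanced <- grayImage(matrix(best$lut[as.integer(img) + 1L],
                               nrow(img), ncol(img)), "uint8")
  new("EnhancementResult", enhanced = enhanced, tauStar = best$tau,
      objectiveValue = best$obj, entropy = best$H, meanBefore = meanBefore,
      meanAfter = best$meanAfter, degenerate = FALSE)
}

## Vectorized exact median of 9 values per pixel by rank counting: the
## median is the element with fewer than 5 strictly-smaller values and at
## least 5 values less-than-or-equal (ties resolved consistently).
median9 <- function(cols) {
  k <- length(cols)
  lt <- le <- vector("list", k)
  for (j in seq_len(k)) {
    lt[[j]] <- le[[j]] <- 0
    for (i in seq_len(k)) {
      lt[[j]] <- lt[[j]] + (cols[[i]] < cols[[j]])
      le[[j]] <- le[[j]] + (cols[[i]] <= cols[[j]])
    }
  }
  half <- (k + 1) / 2
  out <- rep(NA_real_, length(cols[[1]]))
  for (j in seq_len(k)) {
    pick <- is.na(out) & lt[[j]] < half & le[[j]] >= half
    out[pick] <- cols[[j]][pick]
  }
  out
}

#' Median-filter denoising with edge replication
#'
#' Each output pixel is the median of its `window` x `window` neighborhood;
#' borders replicate the nearest edge pixel. Removes salt-and-pepper
#' impulses while preserving vessel edges. The default 3 x 3 window uses a
#' vectorized median network; larger odd windows fall back to a direct
#' per-pixel median.
#'
#' @param img grayscale image (either scale; scale is preserved).
#' @param window odd window side length, >= 3.
#' @return filtered image with the input's scale.
#' @export
medianDenoise <- function(img, window = 3L) {
  window <- as.integer(window)
  if (window < 3L || window %% 2L == 0L)
    stop("'window' must be an odd integer >= 3")
  sc <- imageScale(img)
  r <- (window - 1L) %/% 2L
  nr <- nrow(img); nc <- ncol(img)
  # edge-replicated padding via clamped index vectors
  ri <- pmin(pmax(seq_len(nr + 2L * r) - r, 1L), nr)
  ci <- pmin(pmax(seq_len(nc + 2L * r) - r, 1L), nc)
  P <- img[ri, ci]
  offs <- expand.grid(dr = -r:r, dc = -r:r)
  cols <- lapply(seq_len(nrow(offs)), function(i) {
    as.vector(P[(1L + r + offs$dr[i]):(nr + r + offs$dr[i]),
                (1L + r + offs$dc[i]):(nc + r + offs$dc[i])])
  })
  med <- if (window == 3L) median9(cols) else
    apply(do.call(cbind, cols), 1L, stats::median)
  grayImage(matrix(med, nr, nc), sc)
}
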