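# Independent brute-force oracles: direct transcriptions of the defining
# formulas as plain loops, kept deliberately separate from the package's
# vectorized implementations.

naiveFcmMemberships <- function(X, V, m) {
  X <- as.matrix(X); V <- as.matrix(V)
  c <- nrow(V); N <- nrow(X)
  U <- matrix(0, c, N)
  for (k in seq_len(N)) {
    d2 <- sapply(seq_len(c), function(i) sum((X[k, ] - V[i, ])^2))
    if (any(d2 == 0)) {
      U[d2 == 0, k] <- 1 / sum(d2 == 0)
    } else {
      w <- d2^(-1 / (m - 1))
      U[, k] <- w / sum(w)
    }
  }
  U
}

naiveFcmCentroids <- function(X, U, m) {
  X <- as.matrix(X)
  V <- matrix(0, nrow(U), ncol(X))
  for (i in seq_len(nrow(U))) {
    num <- 0; den <- 0
    for (k in seq_len(ncol(U))) {
      num <- num + U[i, k]^m * X[k, ]
      den <- den + U[i, k]^m
    }
    V[i, ] <- num / den
  }
  V
}

naiveFcmObjective <- function(X, U, V, m) {
  X <- as.matrix(X); V <- as.matrix(V)
  J <- 0
  for (i in seq_len(nrow(U)))
    for (k in seq_len(ncol(U)))
      J <- J + U[i, k]^m * sum((X[k, ] - V[i, ])^2)
  J
}

naiveKernel <- function(x, y, sigma) exp(-sum((x - y)^2) / sigma^2)

naiveKfcmMemberships <- function(X, V, m, sigma) {
  X <- as.matrix(X); V <- as.matrix(V)
  c <- nrow(V); N <- nrow(X)
  U <- matrix(0, c, N)
  for (k in seq_len(N)) {
    dk <- sapply(seq_len(c), function(i) 1 - naiveKernel(X[k, ], V[i, ], sigma))
    if (any(dk == 0)) {
      U[dk == 0, k] <- 1 / sum(dk == 0)
    } else {
      w <- dk^(-1 / (m - 1))
      U[, k] <- w / sum(w)
    }
  }
  U
}

naiveKfcmCentroids <- function(X, U, Vprev, m, sigma) {
  X <- as.matrix(X); Vprev <- as.matrix(Vprev)
  V <- matrix(0, nrow(U), ncol(X))
  for (i in seq_len(nrow(U))) {
    num <- 0; den <- 0
    for (k in seq_len(ncol(U))) {
      w <- U[i, k]^m * naiveKernel(X[k, ], Vprev[i, ], sigma)
      num <- num + w * X[k, ]
      den <- den + w
    }
    V[i, ] <- num / den
  }
  V
}

naiveKfcmObjective <- function(X, U, V, m, sigma) {
  X <- as.matrix(X); V <- as.matrix(V)
  J <- 0
  for (i in seq_len(nrow(U)))
    for (k in seq_len(ncol(U)))
      J <- J + U[i, k]^m * (1 - naiveKernel(X[k, ], V[i, ], sigma))
  2 * J
}

## Binary dilation straight from the set definition: z belongs to the
## dilation iff the reflected element translated to z intersects A.
naiveDilate <- function(A, se) {
  offs <- cbind(which(se@footprint, arr.ind = TRUE)[, 1] - se@origin[1],
                which(se@footprint, arr.ind = TRUE)[, 2] - se@origin[2])
  out <- matrix(0L, nrow(A), ncol(A))
  for (r in seq_len(nrow(A))) for (cc in seq_len(ncol(A))) {
    hit <- FALSE
    for (j in seq_len(nrow(offs))) {
      rr <- r - offs[j, 1]; c2 <- cc - offs[j, 2]
      if (rr >= 1 && rr <= nrow(A) && c2 >= 1 && c2 <= ncol(A) &&
          A[rr, c2] == 1L) { hit <- TRUE; break }
    }
    out[r, cc] <- as.integer(hit)
  }
  out
}

## Grayscale erosion/dilation as windowed min/max with identity padding,
## per-pixel loops.
naiveGrayErode <- function(M, se) {
  offs <- cbind(which(se@footprint, arr.ind = TRUE)[, 1] - se@origin[1],
                which(se@footprint, arr.ind = TRUE)[, 2] - se@origin[2])
  out <- matrix(Inf, nrow(M), ncol(M))
  for (r in seq_len(nrow(M))) for (cc in seq_len(ncol(M))) {
    for (j in seq_len(nrow(offs))) {
      rr <- r - offs[j, 1]; c2 <- cc - offs[j, 2]
      if (rr >= 1 && rr <= nrow(M) && c2 >= 1 && c2 <= ncol(M))
        out[r, cc] <- min(out[r, cc], M[rr, c2])
    }
  }
  out
}

naiveGrayDilate <- function(M, se) {
  offs <- cbind(which(se@footprint, arr.ind = TRUE)[, 1] - se@origin[1],
                which(se@footprint, arr.ind = TRUE)[, 2] - se@origin[2])
  out <- matrix(-Inf, nrow(M), ncol(M))
  for (r in seq_len(nrow(M))) for (cc in seq_len(ncol(M))) {
    for (j in seq_len(nrow(offs))) {
      rr <- r - offs[j, 1]; c2 <- cc - offs[j, 2]
      if (rr >= 1 && rr <= nrow(M) && c2 >= 1 && c2 <= ncol(M))
        out[r, cc] <- max(out[r, cc], M[rr, c2])
    }
  }
  out
}

naiveMedianFilter <- function(M, window) {
  r <- (window - 1) %/% 2
  out <- M
  for (i in seq_len(nrow(M))) for (j in seq_len(ncol(M))) {
    rr <- pmin(pmax((i - r):(i + r), 1), nrow(M))
    cc <- pmin(pmax((j - r):(j + r), 1), ncol(M))
    out[i, j] <- stats::median(M[rr, cc])
  }
  out
}

naiveConfusion <- function(gt, pred) {
  tp <- tn <- fp <- fn <- 0L
  for (i in seq_along(gt)) {
    if (gt[i] == 1L && pred[i] == 1L) tp <- tp + 1L
    else if (gt[i] == 0L && pred[i] == 0L) tn <- tn + 1L
    else if (gt[i] == 0L && pred[i] == 1L) fp <- fp + 1L
    else fn <- fn + 1L
  }
  c(tp = tp, tn = tn, fp = fp, fn = fn)
}

randomMask <- function(n, p = 0.3) matrix(as.integer(runif(n * n) < p), n, n)

grayFromUnit <- function(M) grayImage(M, "unit")

## Connected components (4-connectivity) by flood fill — used to check
## gap-bridging claims about the dilation-based refinement.
countComponents <- function(mask) {
  lab <- matrix(0L, nrow(mask), ncol(mask))
  comp <- 0L
  for (i in seq_len(nrow(mask))) for (j in seq_len(ncol(mask))) {
    if (mask[i, j] == 1L && lab[i, j] == 0L) {
      comp <- comp + 1L
      stack <- list(c(i, j))
      while (length(stack)) {
        p <- stack[[length(stack)]]; stack[[length(stack)]] <- NULL
        if (p[1] < 1 || p[1] > nrow(mask) || p[2] < 1 || p[2] > ncol(mask))
          next
        if (mask[p[1], p[2]] != 1L || lab[p[1], p[2]] != 0L) next
        lab[p[1], p[2]] <- comp
        stack <- c(stack, list(c(p[1] - 1, p[2]), c(p[1] + 1, p[2]),
                               c(p[1], p[2] - 1), c(p[1], p[2] + 1)))
      }
    }
  }
  comp
}
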