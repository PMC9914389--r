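# Fuzzy c-means and its Gaussian-kernel weighted variant (WKFCM).
#
# Standard FCM minimizes J_m = sum_i sum_k u_ik^m ||x_k - v_i||^2 subject
# to column-stochastic memberships, by alternating the closed-form centroid
# and membership updates. WKFCM replaces the squared distance by the
# kernel-induced distance ||Phi(x) - Phi(v)||^2 = 2 (1 - K(x, v)) with
# K(x, y) = exp(-||x - y||^2 / sigma^2); its centroid update is a
# fixed-point step weighted by the kernel evaluated at the previous
# centroids, and the whole iteration is warm-started from a converged
# standard-FCM solution. Convergence is declared when the max-abs
# membership change drops below `tol`. The legacy termination constant
# T = 120 is accepted in configurations for fidelity with the original
# procedure but is non-operative: membership changes never exceed 1.

#' Fuzzy clustering configuration
#'
#' @param c number of clusters (>= 2); default 2 (vessel vs background).
#' @param m fuzzifier (> 1); default 3.
#' @param sigma Gaussian kernel width (> 0); default 0.5.
#' @param maxIter iteration budget; default 150.
#' @param tol max-abs membership change declaring convergence; default 1e-5.
#' @param seed RNG seed for the random membership initialization.
#' @param T legacy termination constant, accepted but non-operative (a
#'   membership change can never exceed 1, so any T > 1 is vacuous).
#' @return a validated list of class `fuzzyConfig`.
#' @export
fuzzyConfig <- function(c = 2L, m = 3, sigma = 0.5, maxIter = 150L,
                        tol = 1e-5, seed = 1L, T = 120) {
  c <- as.integer(c)
  if (c < 2L) stop("'c' must be an integer >= 2")
  if (m <= 1) stop("'m' must exceed 1 (the exponent 1/(m-1) is undefined at m = 1)")
  if (sigma <= 0) stop("'sigma' must be positive")
  if (maxIter < 1L) stop("'maxIter' must be positive")
  if (tol <= 0) stop("'tol' must be positive")
  structure(list(c = c, m = m, sigma = sigma, maxIter = as.integer(maxIter),
                 tol = tol, seed = as.integer(seed), T = T),
            class = "fuzzyConfig")
}

asFeatureMatrix <- function(X) {
  if (is.vector(X)) X <- matrix(X, ncol = 1L)
  if (!is.matrix(X) || !is.numeric(X)) stop("'X' must be a numeric matrix")
  X
}

## Squared Euclidean distances, c x N.
sqDistances <- function(X, V) {
  d2 <- outer(rowSums(V^2), rowSums(X^2), "+") - 2 * V %*% t(X)
  pmax(d2, 0)
}

## Shared inverse-power membership rule: given a c x N matrix of
## non-negative dissimilarities, u_ik = D_ik^(-1/(m-1)) / sum_j D_jk^(...).
## Points with a zero dissimilarity split their membership equally among
## the zero-dissimilarity clusters (the coincident-centroid singularity).
membershipFromDissimilarity <- function(D, expo) {
  W <- D^(-expo)
  sing <- !is.finite(W)                 # zero (or overflow-small) dissimilarity
  anySing <- colSums(sing) > 0L
  if (any(anySing)) {
    W[, anySing] <- 0
    W[sing] <- 1
  }
  sweep(W, 2L, colSums(W), "/")
}

#' Standard FCM membership update
#'
#' `u_ik` is proportional to `||x_k - v_i||^(-2/(m-1))`, normalized over
#' clusters; a point coinciding with a centroid takes membership 1 there.
#'
#' @param X N x D feature matrix (or numeric vector, taken as N x 1).
#' @param V c x D centroid matrix.
#' @param m fuzzifier, > 1.
#' @return c x N membership matrix with unit column sums.
#' @export
fcmMemberships <- function(X, V, m) {
  if (m <= 1) stop("'m' must exceed 1")
  X <- asFeatureMatrix(X); V <- asFeatureMatrix(V)
  membershipFromDissimilarity(sqDistances(X, V), 1 / (m - 1))
}

#' Standard FCM centroid update
#'
#' `v_i = sum_k u_ik^m x_k / sum_k u_ik^m`: the membership-power weighted
#' mean, always inside the convex hull of the data.
#'
#' @inheritParams fcmMemberships
#' @param U c x N membership matrix.
#' @return c x D centroid matrix.
#' @export
fcmCentroids <- function(X, U, m) {
  X <- asFeatureMatrix(X)
  W <- U^m
  mass <- rowSums(W)
  if (any(mass <= 0)) stop("degenerate cluster: zero total membership mass")
  sweep(W %*% X, 1L, mass, "/")
}

#' Standard FCM objective
#'
#' `J_m = sum_i sum_k u_ik^m ||x_k - v_i||^2`; non-negative.
#'
#' @inheritParams fcmCentroids
#' @param V c x D centroid matrix.
#' @return scalar objective value.
#' @export
fcmObjective <- function(X, U, V, m) {
  X <- asFeatureMatrix(X); V <- asFeatureMatrix(V)
  sum(U^m * sqDistances(X, V))
}

#' Gaussian kernel
#'
#' `K(x, y) = exp(-||x - y||^2 / sigma^2)`, in (0, 1] with K(x, x) = 1.
#'
#' @param x,y numeric feature vectors of equal length.
#' @param sigma kernel width, > 0.
#' @return scalar kernel value.
#' @export
gaussianKernel <- function(x, y, sigma) {
  if (sigma <= 0) stop("'sigma' must be positive")
  exp(-sum((x - y)^2) / sigma^2)
}

## c x N matrix of 1 - K(x_k, v_i), computed as -expm1(-d^2/sigma^2) so the
## large-sigma regime keeps full relative precision (the sigma -> Inf limit
## must reduce exactly to squared distances up to a common factor).
oneMinusKernel <- function(X, V, sigma) {
  -expm1(-sqDistances(X, V) / sigma^2)
}

#' Kernel FCM membership update
#'
#' `u_ik` proportional to `(1 - K(x_k, v_i))^(-1/(m-1))`, normalized over
#' clusters, with the same coincidence singularity rule as standard FCM
#' (K -> 1 gives membership 1).
#'
#' @inheritParams fcmMemberships
#' @param sigma Gaussian kernel width, > 0.
#' @return c x N membership matrix with unit column sums.
#' @export
kfcmMemberships <- function(X, V, m, sigma) {
  if (m <= 1) stop("'m' must exceed 1")
  if (sigma <= 0) stop("'sigma' must be positive")
  X <- asFeatureMatrix(X); V <- asFeatureMatrix(V)
  membershipFromDissimilarity(oneMinusKernel(X, V, sigma), 1 / (m - 1))
}

#' Kernel FCM centroid update (fixed-point step)
#'
#' `v_i = sum_k u_ik^m K(x_k, v_i^prev) x_k / sum_k u_ik^m K(x_k, v_i^prev)`
#' — the kernel weights are evaluated at the previous centroids, making the
#' update an explicit fixed-point step.
#'
#' @inheritParams kfcmMemberships
#' @param U c x N membership matrix.
#' @param Vprev c x D previous centroids (inside the kernel weights).
#' @return c x D centroid matrix.
#' @export
kfcmCentroids <- function(X, U, Vprev, m, sigma) {
  X <- asFeatureMatrix(X); Vprev <- asFeatureMatrix(Vprev)
  W <- U^m * (1 - oneMinusKernel(X, Vprev, sigma))
  mass <- rowSums(W)
  if (any(mass <= .Machine$double.xmin))
    stop("degenerate cluster: vanishing kernel-weighted mass")
  sweep(W %*% X, 1L, mass, "/")
}

#' Kernel FCM objective
#'
#' `J = 2 sum_i sum_k u_ik^m (1 - K(x_k, v_i))`, the kernel-space squared
#' error (since `||Phi(x) - Phi(v)||^2 = 2 (1 - K(x, v))`).
#'
#' @inheritParams kfcmCentroids
#' @param V c x D centroid matrix.
#' @return scalar objective value.
#' @export
kfcmObjective <- function(X, U, V, m, sigma) {
  X <- asFeatureMatrix(X); V <- asFeatureMatrix(V)
  2 * sum(U^m * oneMinusKernel(X, V, sigma))
}

## Flat-Dirichlet random membership initialization (c x N), seeded.
randomMemberships <- function(c, N) {
  E <- matrix(stats::rexp(c * N), c, N)
  sweep(E, 2L, colSums(E), "/")
}

#' Run standard fuzzy c-means
#'
#' Memberships are initialized uniformly at random on the simplex (seeded),
#' then centroid and membership updates alternate until the max-abs
#' membership change falls below `tol` or the iteration budget is spent.
#' The objective is recorded after every full update pair and is
#' non-increasing.
#'
#' @param X N x D feature matrix (or numeric vector); N must be >= the
#'   cluster count.
#' @param config a [fuzzyConfig()].
#' @return a [FuzzyState-class].
#' @export
runFCM <- function(X, config = fuzzyConfig()) {
  X <- asFeatureMatrix(X)
  N <- nrow(X)
  if (N < config$c) stop("need at least as many points as clusters")
  U <- withSeed(config$seed, randomMemberships(config$c, N))
  trace <- numeric(0); dev <- numeric(0)
  delta <- Inf; iter <- 0L
  while (iter < config$maxIter) {
    iter <- iter + 1L
    V <- fcmCentroids(X, U, config$m)
    Unew <- fcmMemberships(X, V, config$m)
    delta <- max(abs(Unew - U))
    U <- Unew
    trace[iter] <- fcmObjective(X, U, V, config$m)
    dev[iter] <- max(abs(colSums(U) - 1))
    if (delta < config$tol) break
  }
  new("FuzzyState", centroids = V, memberships = U, objectiveTrace = trace,
      colsumDev = dev, iterationsRun = iter, converged = delta < config$tol,
      deltaFinal = delta, method = "fcm")
}

## Min-max normalization of each feature column onto [0, 1] (the unit
## hypercube); constant columns map to 0.
normalizeHypercube <- function(X) {
  X <- asFeatureMatrix(X)
  lo <- apply(X, 2L, min); hi <- apply(X, 2L, max)
  span <- ifelse(hi > lo, hi - lo, 1)
  sweep(sweep(X, 2L, lo, "-"), 2L, span, "/")
}

#' Run weighted-kernel fuzzy c-means
#'
#' The warm-started kernel procedure: (1) features are normalized to the
#' unit hypercube; (2) standard FCM ([runFCM()]) supplies initial
#' centroids; (3) kernel membership and fixed-point centroid updates
#' alternate, with the max-abs membership change `Delta` deciding
#' termination (`Delta < tol`, or the iteration budget). The terminal state
#' is self-consistent: reapplying the two updates moves memberships by less
#' than `tol`.
#'
#' @inheritParams runFCM
#' @param normalize normalize features to the unit hypercube first
#'   (default TRUE, as the procedure prescribes). Disable only when the
#'   caller has already normalized.
#' @return a [FuzzyState-class] (centroids on the normalized scale when
#'   `normalize = TRUE`).
#' @export
runWKFCM <- function(X, config = fuzzyConfig(), normalize = TRUE) {
  X <- asFeatureMatrix(X)
  if (normalize) X <- normalizeHypercube(X)
  warm <- runFCM(X, config)
  V <- centroids(warm)
  U <- kfcmMemberships(X, V, config$m, config$sigma)
  trace <- numeric(0); dev <- numeric(0)
  delta <- Inf; iter <- 0L
  while (iter < config$maxIter) {
    iter <- iter + 1L
    V <- kfcmCentroids(X, U, V, config$m, config$sigma)
    Unew <- kfcmMemberships(X, V, config$m, config$sigma)
    delta <- max(abs(Unew - U))
    U <- Unew
    trace[iter] <- kfcmObjective(X, U, V, config$m, config$sigma)
    dev[iter] <- max(abs(colSums(U) - 1))
    if (delta < config$tol) break
  }
  new("FuzzyState", centroids = V, memberships = U, objectiveTrace = trace,
      colsumDev = dev, iterationsRun = iter, converged = delta < config$tol,
      deltaFinal = delta, method = "wkfcm")
}
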