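test_that("FCM memberships follow the inverse-distance closed form", {
  # hand evaluation: x = 0, centroids (1, 3), m = 2
  U <- fcmMemberships(matrix(0), matrix(c(1, 3), 2, 1), m = 2)
  expect_equal(U[, 1], c(0.9, 0.1))
  # equidistant point splits evenly for any m
  for (m in c(1.5, 2, 3, 7)) {
    U <- fcmMemberships(matrix(0.5), matrix(c(0, 1), 2, 1), m)
    expect_equal(U[, 1], c(0.5, 0.5))
  }
  # coincidence singularity
  U <- fcmMemberships(matrix(1), matrix(c(1, 3), 2, 1), 2)
  expect_equal(U[, 1], c(1, 0))
  expect_error(fcmMemberships(matrix(0), matrix(c(1, 3), 2, 1), 1), "m")
})

test_that("FCM centroid update reduces to means for crisp memberships", {
  X <- matrix(c(0, 0.1, 0.9, 1.0), ncol = 1)
  U <- rbind(c(1, 1, 0, 0), c(0, 0, 1, 1))
  V <- fcmCentroids(X, U, m = 2)
  expect_equal(V[, 1], c(0.05, 0.95))
  # uniform memberships collapse both centroids onto the global mean
  U2 <- matrix(0.5, 2, 4)
  expect_equal(fcmCentroids(X, U2, 3)[, 1], rep(mean(X), 2))
})

test_that("fcm/kfcm operators agree with naive-loop oracles", {
  set.seed(31)
  for (i in 1:20) {
    N <- sample(5:50, 1); D <- sample(1:3, 1); c <- sample(2:4, 1)
    m <- runif(1, 1.3, 4); sigma <- runif(1, 0.2, 2)
    X <- matrix(runif(N * D), N, D)
    V <- matrix(runif(c * D), c, D)
    U <- matrix(rexp(c * N), c, N); U <- sweep(U, 2, colSums(U), "/")

    expect_equal(fcmMemberships(X, V, m), naiveFcmMemberships(X, V, m),
                 tolerance = 1e-12)
    expect_equal(fcmCentroids(X, U, m), naiveFcmCentroids(X, U, m),
                 tolerance = 1e-12)
    expect_equal(fcmObjective(X, U, V, m), naiveFcmObjective(X, U, V, m),
                 tolerance = 1e-12)
    expect_equal(kfcmMemberships(X, V, m, sigma),
                 naiveKfcmMemberships(X, V, m, sigma), tolerance = 1e-12)
    expect_equal(kfcmCentroids(X, U, V, m, sigma),
                 naiveKfcmCentroids(X, U, V, m, sigma), tolerance = 1e-12)
    expect_equal(kfcmObjective(X, U, V, m, sigma),
                 naiveKfcmObjective(X, U, V, m, sigma), tolerance = 1e-12)
  }
})

test_that("objective closed forms hold at exact fits", {
  X <- matrix(c(0, 1), ncol = 1)
  V <- matrix(c(0, 1), 2, 1)
  U <- rbind(c(1, 0), c(0, 1))
  expect_equal(fcmObjective(X, U, V, 2), 0)
  expect_equal(kfcmObjective(X, U, V, 2, 0.5), 0)
  # single point at distance 1, one cluster, u = 1 -> J = 1
  expect_equal(fcmObjective(matrix(1), matrix(1, 1, 1), matrix(0), 2), 1)
  # 1 - K = 0.5 with u = 1 -> kernel objective 2 * 0.5 = 1
  sigma <- 1 / sqrt(log(2)) # so K(0,1) = 0.5
  expect_equal(kfcmObjective(matrix(1), matrix(1, 1, 1), matrix(0), 3, sigma), 1)
})

test_that("Gaussian kernel matches closed forms and is symmetric", {
  expect_equal(gaussianKernel(c(1, 2), c(1, 2), 0.7), 1)
  expect_equal(gaussianKernel(0, 0.5, 0.5), exp(-1))
  set.seed(32)
  for (i in 1:10) {
    x <- runif(3); y <- runif(3); s <- runif(1, 0.1, 2)
    expect_equal(gaussianKernel(x, y, s), gaussianKernel(y, x, s))
    expect_gt(gaussianKernel(x, y, s), 0)
    expect_lte(gaussianKernel(x, y, s), 1)
  }
  expect_error(gaussianKernel(0, 1, 0), "positive")
})

test_that("kernel memberships hit hand-computed values and singularities", {
  # numeric case x = 0, V = (1, 3), m = 2, sigma = 2 against direct formula
  U <- kfcmMemberships(matrix(0), matrix(c(1, 3), 2, 1), 2, 2)
  d1 <- 1 - exp(-1 / 4); d2 <- 1 - exp(-9 / 4)
  expect_equal(U[, 1], c(1 / d1, 1 / d2) / (1 / d1 + 1 / d2),
               tolerance = 1e-12)
  # coincidence -> membership 1; equidistance -> 0.5/0.5
  expect_equal(kfcmMemberships(matrix(1), matrix(c(1, 3), 2, 1), 2, 1)[, 1],
               c(1, 0))
  expect_equal(kfcmMemberships(matrix(2), matrix(c(1, 3), 2, 1), 3, 0.7)[, 1],
               c(0.5, 0.5))
})

test_that("kernel centroids reduce to FCM centroids as sigma grows", {
  set.seed(33)
  X <- matrix(runif(30), ncol = 1)
  U <- matrix(rexp(60), 2); U <- sweep(U, 2, colSums(U), "/")
  V <- matrix(c(0.2, 0.8), 2, 1)
  expect_equal(kfcmCentroids(X, U, V, 3, 1e6), fcmCentroids(X, U, 3),
               tolerance = 1e-9)
  # crisp memberships with coincident points leave the centroid fixed
  Xc <- matrix(rep(0.4, 5), ncol = 1)
  Uc <- rbind(rep(1, 5), rep(0, 5))
  expect_equal(kfcmCentroids(Xc, pmax(Uc, 1e-12), matrix(c(0.4, 0.9), 2, 1),
                             2, 0.5)[1, 1], 0.4)
})

test_that("runFCM recovers well-separated blobs and is deterministic", {
  X <- c(0, 0.05, 0.95, 1.0)
  st <- runFCM(X, fuzzyConfig(c = 2, m = 2, seed = 5))
  V <- sort(centroids(st)[, 1])
  expect_lt(abs(V[1] - 0.025), 0.05)
  expect_lt(abs(V[2] - 0.975), 0.05)
  lab <- apply(memberships(st), 2, which.max)
  expect_equal(lab[1], lab[2]); expect_equal(lab[3], lab[4])
  expect_false(lab[1] == lab[3])

  # bitwise determinism under a fixed seed
  st2 <- runFCM(X, fuzzyConfig(c = 2, m = 2, seed = 5))
  expect_identical(memberships(st), memberships(st2))
  expect_identical(centroids(st), centroids(st2))

  # duplicating every point leaves the centroids unchanged
  st3 <- runFCM(rep(X, each = 2), fuzzyConfig(c = 2, m = 2, seed = 5))
  expect_equal(sort(centroids(st3)[, 1]), sort(centroids(st)[, 1]),
               tolerance = 1e-3)
})

test_that("runFCM keeps memberships normalized with a non-increasing objective", {
  set.seed(34)
  X <- runif(300)
  st <- runFCM(X, fuzzyConfig(c = 3, m = 2.5, seed = 7))
  expect_true(all(st@colsumDev <= 1e-9))
  tr <- objectiveTrace(st)
  expect_true(all(diff(tr) <= 1e-9))
  expect_error(runFCM(c(0.1), fuzzyConfig(c = 2)), "at least as many")
})

test_that("FCM agrees with an independent library implementation", {
  skip_if_not_installed("e1071")
  set.seed(35)
  X <- matrix(c(rnorm(60, 0, 0.05), rnorm(60, 1, 0.05)), ncol = 1)
  st <- runFCM(X, fuzzyConfig(c = 2, m = 2, seed = 1, tol = 1e-8,
                              maxIter = 300))
  ref <- e1071::cmeans(X, centers = 2, m = 2, iter.max = 300)
  expect_equal(sort(centroids(st)[, 1]), sort(as.vector(ref$centers)),
               tolerance = 1e-3)
})

test_that("WKFCM matches FCM in the large-sigma kernel limit", {
  set.seed(36)
  X <- runif(400)
  cfgF <- fuzzyConfig(c = 2, m = 3, seed = 3, tol = 1e-7)
  cfgK <- fuzzyConfig(c = 2, m = 3, sigma = 1e6, seed = 3, tol = 1e-7)
  stF <- runFCM(matrix((X - min(X)) / (max(X) - min(X)), ncol = 1), cfgF)
  stK <- runWKFCM(X, cfgK)
  err <- min(max(abs(memberships(stK) - memberships(stF))),
             max(abs(memberships(stK) - memberships(stF)[2:1, ])))
  expect_lt(err, 1e-3)
})

test_that("WKFCM terminal state is a fixed point and label-permutation invariant", {
  set.seed(37)
  X <- c(rnorm(200, 0.12, 0.03), rnorm(60, 0.8, 0.05))
  X <- pmin(pmax(X, 0), 1)
  cfg <- fuzzyConfig(c = 2, m = 3, sigma = 0.5, seed = 11)
  st <- runWKFCM(X, cfg)
  expect_true(st@converged)
  expect_true(all(st@colsumDev <= 1e-9))

  # self-consistency: one more update pair moves memberships < tol
  Xn <- matrix((X - min(X)) / (max(X) - min(X)), ncol = 1)
  V2 <- kfcmCentroids(Xn, memberships(st), centroids(st), cfg$m, cfg$sigma)
  U2 <- kfcmMemberships(Xn, V2, cfg$m, cfg$sigma)
  expect_lt(max(abs(U2 - memberships(st))), cfg$tol)

  # crisp assignment recovers the generative modes almost perfectly
  lab <- apply(memberships(st), 2, which.max)
  truth <- rep(1:2, c(200, 60))
  vesselCl <- which.max(centroids(st)[, 1])
  acc <- mean((lab == vesselCl) == (truth == 2))
  expect_gte(acc, 0.99)
  V <- sort(centroids(st)[, 1])
  expect_lt(V[1], 0.45); expect_gt(V[2], 0.45)
})

test_that("cluster relabeling of the seed permutes the solution, nothing more", {
  set.seed(38)
  X <- c(rnorm(50, 0.2, 0.05), rnorm(50, 0.7, 0.05))
  st1 <- runFCM(X, fuzzyConfig(c = 2, m = 2, seed = 9))
  st2 <- runFCM(X, fuzzyConfig(c = 2, m = 2, seed = 10))
  # same partition up to label order
  agree <- min(max(abs(memberships(st1) - memberships(st2))),
               max(abs(memberships(st1) - memberships(st2)[2:1, ])))
  expect_lt(agree, 1e-3)
})

test_that("configuration validation rejects undefined parameters", {
  expect_error(fuzzyConfig(c = 1), ">= 2")
  expect_error(fuzzyConfig(m = 1), "undefined")
  expect_error(fuzzyConfig(sigma = 0), "positive")
  expect_error(fuzzyConfig(tol = 0), "positive")
})
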