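test_that("structuring elements have symmetric footprints of the right size", {
  d3 <- structuringElement("disk", 3)
  expect_equal(sum(d3@footprint), 5L) # 4-connected cross
  s7 <- structuringElement("square", 7)
  expect_equal(dim(s7@footprint), c(7L, 7L))
  expect_true(all(s7@footprint))
  expect_error(structuringElement("disk", 4), "odd")
  expect_error(structuringElement("square", 0), "odd|positive")
  # symmetry: footprint equals its 180-degree rotation
  d7 <- structuringElement("disk", 7)
  fp <- d7@footprint
  expect_identical(fp, fp[rev(seq_len(nrow(fp))), rev(seq_len(ncol(fp)))])
})

test_that("binary dilation matches the set-definition oracle exactly", {
  ses <- list(structuringElement("disk", 3), structuringElement("disk", 5),
              structuringElement("square", 3))
  set.seed(21)
  for (i in 1:25) {
    A <- randomMask(12, runif(1, 0.05, 0.5))
    se <- ses[[1 + i %% 3]]
    expect_identical(morphoDilate(A, se), naiveDilate(A, se))
  }
  # single center pixel -> the footprint stamped
  A <- matrix(0L, 7, 7); A[4, 4] <- 1L
  out <- morphoDilate(A, structuringElement("square", 3))
  expect_equal(sum(out), 9L)
  expect_true(all(out[3:5, 3:5] == 1L))
  # empty mask dilates to empty
  expect_true(all(morphoDilate(matrix(0L, 5, 5),
                               structuringElement("disk", 3)) == 0L))
})

test_that("erosion/dilation complement duality holds on random masks", {
  set.seed(22)
  for (i in 1:15) {
    A <- randomMask(10, 0.4)
    se <- structuringElement(c("disk", "square")[1 + i %% 2], c(3, 5)[1 + i %% 2])
    expect_identical(morphoErode(A, se), 1L - morphoDilate(1L - A, se))
  }
})

test_that("grayscale erosion and dilation match windowed min/max oracles", {
  set.seed(23)
  for (i in 1:10) {
    M <- grayFromUnit(matrix(runif(100), 10, 10))
    se <- structuringElement("disk", 5)
    expect_equal(morphoErode(M, se)[, ], naiveGrayErode(M, se),
                 ignore_attr = TRUE)
    expect_equal(morphoDilate(M, se)[, ], naiveGrayDilate(M, se),
                 ignore_attr = TRUE)
  }
  # constants are fixed points; a dark pit spreads under erosion
  flat <- grayImage(matrix(200, 6, 6), "uint8")
  se3 <- structuringElement("square", 3)
  expect_equal(morphoErode(flat, se3)[, ], flat[, ], ignore_attr = TRUE)
  pit <- matrix(255, 9, 9); pit[5, 5] <- 0
  er <- morphoErode(grayImage(pit, "uint8"), se3)
  expect_true(all(er[4:6, 4:6] == 0))
  expect_equal(sum(er == 0), 9)
})

test_that("opening is anti-extensive, idempotent, and removes small spots", {
  se <- structuringElement("disk", 5)
  set.seed(24)
  for (i in 1:8) {
    M <- grayFromUnit(matrix(runif(144), 12, 12))
    op <- morphoOpen(M, se)
    expect_true(all(op <= M + 1e-12))
    expect_equal(morphoOpen(op, se)[, ], op[, ], ignore_attr = TRUE)
  }
  flat <- grayImage(matrix(0.3, 11, 11), "unit")
  expect_equal(morphoOpen(flat, se)[, ], flat[, ], ignore_attr = TRUE)
  spot <- matrix(0.2, 11, 11); spot[6, 6] <- 0.9
  op <- morphoOpen(grayImage(spot, "unit"), se)
  expect_true(all(op == 0.2))
})

test_that("white top-hat isolates small bright features and reconstructs", {
  se <- structuringElement("disk", 5)
  flat <- grayImage(matrix(0.4, 9, 9), "unit")
  expect_true(all(whiteTopHatTransform(flat, se) == 0))

  spot <- matrix(0.1, 11, 11); spot[6, 6] <- 0.1 + 100 / 255
  wth <- whiteTopHatTransform(grayImage(spot, "unit"), se)
  expect_equal(wth[6, 6], 100 / 255)
  expect_true(all(wth[-(6 + 10 * (6 - 1))] >= 0))
  expect_equal(sum(wth > 0), 1)

  set.seed(25)
  for (i in 1:8) {
    M <- grayFromUnit(matrix(runif(100), 10, 10))
    wth <- whiteTopHatTransform(M, se)
    expect_true(all(wth >= 0))
    # exact reconstruction: f = opening(f) + WTH(f)
    expect_equal(morphoOpen(M, se)[, ] + wth[, ], M[, ], ignore_attr = TRUE)
  }
})

test_that("black top-hat is the white top-hat of the inverted image", {
  se <- structuringElement("disk", 3)
  flat <- grayImage(matrix(0.7, 8, 8), "unit")
  expect_true(all(blackTopHatTransform(flat, se) == 0))

  pit <- matrix(0.8, 9, 9); pit[5, 5] <- 0.2
  bth <- blackTopHatTransform(grayImage(pit, "unit"), se)
  expect_gt(bth[5, 5], 0)
  expect_equal(sum(bth > 0), 1)

  set.seed(26)
  for (i in 1:8) {
    M <- grayFromUnit(matrix(runif(100), 10, 10))
    inv <- grayImage(1 - unclass(M)[, ], "unit")
    expect_equal(blackTopHatTransform(M, se)[, ],
                 whiteTopHatTransform(inv, se)[, ], ignore_attr = TRUE)
  }
})

test_that("dilation is extensive and monotone for origin-containing elements", {
  set.seed(27)
  se <- structuringElement("disk", 3)
  for (i in 1:10) {
    A <- randomMask(10, 0.3)
    dA <- morphoDilate(A, se)
    expect_true(all(dA >= A))
    B <- A; B[A == 0L][1] <- 1L      # A strictly inside B
    expect_true(all(morphoDilate(B, se) >= dA))
  }
})
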