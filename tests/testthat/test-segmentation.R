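test_that("metal thresholding matches the analytic disk pixel count", {
  # 8 mm disk at 0.39 mm spacing on a 96 px crop
  n <- 96; sp <- 0.39; ctr <- (n + 1) / 2
  xm <- (matrix(1:n, n, n, byrow = TRUE) - ctr) * sp
  ym <- (matrix(1:n, n, n) - ctr) * sp
  inside <- xm^2 + ym^2 <= 4^2
  img <- ct_image(matrix(40, n, n) + inside * 7960, c(sp, sp))
  mask <- segment_metal(img, hu_threshold = 2000, min_label_px = 100)
  brute <- sum(inside)           # centre-in-circle count, same grid
  expect_identical(sum(mask$pixels), brute)
  expect_lt(abs(sum(mask$pixels) - pi * (4 / sp)^2) / (pi * (4 / sp)^2), 0.05)
})

test_that("the label size filter removes small bright noise", {
  img <- matrix(0, 64, 64)
  img[10:33, 10:33] <- 3000          # ~576 px block
  img[50:56, 50:56] <- 3000          # 49 px blob, below the 100 px filter
  mask <- segment_metal(ct_image(img, c(1, 1)))
  expect_true(all(mask$pixels[10:33, 10:33]))
  expect_false(any(mask$pixels[50:56, 50:56]))

  expect_error(segment_metal(ct_image(matrix(-1000, 16, 16), c(1, 1))),
               class = "marref_no_metal")
})

test_that("the near/far split is an exact mm-distance partition", {
  set.seed(17)
  px <- matrix(runif(120 * 120) < 0.3, 120, 120)
  mask <- region_mask(px, "tissue", spacing_mm = c(0.39, 0.39))
  ctr <- c(55.2, 63.8)
  nf <- split_near_far(mask, ctr, radius_mm = 20)
  # partition
  expect_identical(nf$near$pixels | nf$far$pixels, px)
  expect_false(any(nf$near$pixels & nf$far$pixels))
  # exhaustive distance oracle
  for (k in sample(which(px), 200)) {
    rc <- arrayInd(k, dim(px))
    d <- sqrt(sum(((rc - ctr) * 0.39)^2))
    expect_identical(nf$near$pixels[k], d < 20)
  }
  # mask entirely inside the radius: far empty
  tiny <- region_mask(matrix(c(TRUE, rep(FALSE, 99)), 10, 10), "bone",
                      spacing_mm = c(1, 1))
  nf2 <- split_near_far(tiny, c(1, 1), radius_mm = 50)
  expect_equal(sum(nf2$far$pixels), 0)
})

test_that("overlap ratio follows its defining formula and symmetry", {
  a <- matrix(FALSE, 20, 20); a[1:10, 1:10] <- TRUE        # 100 px
  b <- matrix(FALSE, 20, 20); b[6:15, 1:10] <- TRUE        # 100 px, 50 shared
  expect_equal(overlap_ratio(a, a), 100)
  expect_equal(overlap_ratio(a, !a & cbind(matrix(TRUE, 20, 10), matrix(FALSE, 20, 10))), 0)
  expect_equal(overlap_ratio(a, b), 100 * 50 / 150)
  expect_equal(overlap_ratio(a, b), overlap_ratio(b, a))
  expect_equal(dice_coefficient(a, b), 2 * 50 / 200)
  expect_error(overlap_ratio(matrix(FALSE, 2, 2), matrix(FALSE, 2, 2)),
               class = "marref_empty_region")
})

test_that("automatic segmentation recovers the noiseless ground truth", {
  fx <- noiseless_seg_fixture()
  gt <- fx$ref$masks
  mex <- marref:::dilate_mask(gt$metal$pixels, 2)
  jac <- function(a, b) sum(a & b) / sum(a | b)
  expect_gte(jac(fx$seg$bone$pixels, gt$bone$pixels & !mex), 0.98)
  expect_gte(jac(fx$seg$tissue$pixels, gt$tissue$pixels & !mex), 0.98)
  # pairwise disjoint, and metal excluded from both
  expect_false(any(fx$seg$bone$pixels & fx$seg$tissue$pixels))
  expect_false(any(fx$seg$bone$pixels & fx$metal$pixels))
  expect_false(any(fx$seg$tissue$pixels & fx$metal$pixels))
})

test_that("segmentation masks from one scan are reused on its twin", {
  rep1 <- scenario_report(0)
  # the non-MAR and MAR roles share the evaluation masks: identical counts
  m <- rep1$models
  for (st in c("bone", "tissue")) for (zn in c("whole", "near", "far")) {
    sel <- m$structure == st & m$zone == zn
    expect_equal(m$n_px[sel & m$role == "nonmar"], m$n_px[sel & m$role == "mar"])
  }
})
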