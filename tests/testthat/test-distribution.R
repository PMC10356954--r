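test_that("histogram counts are conserved and match brute-force binning", {
  set.seed(23)
  px <- matrix(rnorm(60 * 60, 100, 35), 60, 60)
  msk <- matrix(runif(60 * 60) < 0.4, 60, 60)
  img <- ct_image(px, c(1, 1))
  mask <- region_mask(msk, "tissue", spacing_mm = c(1, 1))
  h <- region_histogram(img, mask, bin_width_hu = 2)
  expect_equal(sum(h$counts), sum(msk))
  # exhaustive per-pixel binning oracle
  vals <- px[msk]
  brute <- integer(length(h$counts))
  for (v in vals) {
    i <- min(floor((v - h$bin_edges[1]) / 2) + 1, length(brute))
    brute[i] <- brute[i] + 1L
  }
  expect_identical(h$counts, brute)

  # constant region: a single occupied bin
  img2 <- ct_image(matrix(40, 10, 10), c(1, 1))
  h2 <- region_histogram(img2, region_mask(matrix(TRUE, 10, 10), "tissue",
                                           spacing_mm = c(1, 1)))
  expect_equal(sum(h2$counts > 0), 1)

  expect_error(region_histogram(img, region_mask(matrix(FALSE, 60, 60), "bone",
                                                 spacing_mm = c(1, 1))),
               class = "marref_empty_region")
})

test_that("a noiseless Gaussian histogram is recovered to near machine precision", {
  x <- seq(-400, 400, by = 1)
  counts <- round(5000 * exp(-(x - 35)^2 / (2 * 60^2)))
  h <- structure(list(bin_edges = c(x - 0.5, max(x) + 0.5), counts = counts,
                      bin_width_hu = 1,
                      source = list(structure = "bone", zone = "whole", role = "x")),
                 class = "region_histogram")
  g <- fit_gaussian(h)
  expect_equal(g$centroid_hu, 35, tolerance = 1e-5)
  expect_equal(g$sigma_hu, 60, tolerance = 1e-4)
  expect_true(g$converged)
})

test_that("fitted parameters recover the generating distribution from samples", {
  set.seed(41)
  v <- rnorm(25000, 40, 15)
  img <- ct_image(matrix(v, 125, 200), c(1, 1))
  mask <- region_mask(matrix(TRUE, 125, 200), "tissue", spacing_mm = c(1, 1))
  g <- fit_gaussian(region_histogram(img, mask, 1))
  expect_lt(abs(g$centroid_hu - 40), 0.5)
  expect_lt(abs(g$sigma_hu / 15 - 1), 0.02)
  # stability across bin widths 1-5 HU
  for (w in c(2, 5)) {
    gw <- fit_gaussian(region_histogram(img, mask, w))
    expect_lt(abs(gw$centroid_hu - g$centroid_hu), 0.5)
    expect_lt(abs(gw$sigma_hu / g$sigma_hu - 1), 0.02)
  }
})

test_that("degenerate histograms are refused", {
  img <- ct_image(matrix(40, 10, 10), c(1, 1))
  h <- region_histogram(img, region_mask(matrix(TRUE, 10, 10), "tissue",
                                         spacing_mm = c(1, 1)))
  expect_error(fit_gaussian(h), class = "marref_degenerate_distribution")
})

test_that("the two FWHM conventions differ by exactly a factor of two", {
  g <- marref:::new_gaussian_model(0, 100, 1, 0, "least_squares", TRUE, 1)
  expect_equal(fwhm(g, "paper"), sqrt(2 * log(2)) * 100)        # 117.741...
  expect_equal(fwhm(g, "conventional"), 2 * sqrt(2 * log(2)) * 100)
  expect_equal(fwhm(g, "conventional") / fwhm(g, "paper"), 2)
  expect_error(fwhm(marref:::new_gaussian_model(0, -1, 1, 0, "x", TRUE, 1)),
               class = "marref_bad_input")
})

test_that("the centroid is the fitted mean and shifts with the data", {
  set.seed(43)
  v <- rnorm(25000, 1035, 80)
  img <- ct_image(matrix(v, 125, 200), c(1, 1))
  mask <- region_mask(matrix(TRUE, 125, 200), "bone", spacing_mm = c(1, 1))
  g <- fit_gaussian(region_histogram(img, mask, 1))
  expect_equal(centroid(g), g$centroid_hu)
  expect_lt(abs(centroid(g) - 1035), 1)
  # uniform HU shift moves mu and leaves sigma
  g2 <- fit_gaussian(region_histogram(ct_image(img$pixels + 250, c(1, 1)), mask, 1))
  expect_equal(g2$centroid_hu - g$centroid_hu, 250, tolerance = 0.1)
  expect_equal(g2$sigma_hu, g$sigma_hu, tolerance = 0.01 * g$sigma_hu)
})
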