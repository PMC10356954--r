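gm <- function(mu, sigma) marref:::new_gaussian_model(mu, sigma, 100, 0,
                                                      "least_squares", TRUE, 1000)

test_that("ratio metrics are the four reference quotients", {
  k <- sqrt(2 * log(2))
  r <- ratio_metrics(gm(50, 180 / k), gm(50, 120 / k), gm(50, 100 / k))
  expect_equal(r$fwhm_nm, 1.8)
  expect_equal(r$fwhm_m, 1.2)
  expect_equal(r$cent_nm, 1)
  expect_equal(r$cent_m, 1)
  ident <- ratio_metrics(gm(40, 15), gm(40, 15), gm(40, 15))
  expect_equal(unlist(ident), c(fwhm_nm = 1, fwhm_m = 1, cent_nm = 1, cent_m = 1))
  expect_error(ratio_metrics(gm(40, 15), gm(40, 15), gm(0, 15)),
               class = "marref_division_by_zero")
})

test_that("classification reads the FWHM comparison as published", {
  expect_equal(classify_mar_effect(list(fwhm_nm = 1.32, fwhm_m = 1.16)),
               "artifact_reduced")
  expect_equal(classify_mar_effect(list(fwhm_nm = 1.81, fwhm_m = 2.18)),
               "mar_distortion")
  expect_equal(classify_mar_effect(list(fwhm_nm = 1.00, fwhm_m = 1.00)), "neutral")
  expect_equal(classify_mar_effect(list(fwhm_nm = 1.01, fwhm_m = 1.00)), "neutral")
  expect_equal(classify_mar_effect(list(fwhm_nm = 1.01, fwhm_m = 1.00), epsilon = 0),
               "artifact_reduced")
})

test_that("an identical triple yields exact unit ratios and full overlap", {
  rep1 <- identity_report()
  m <- rep1$metrics
  expect_equal(nrow(m), 6)
  expect_true(all(m$fwhm_nm == 1 & m$fwhm_m == 1 & m$cent_nm == 1 & m$cent_m == 1))
  expect_true(all(m$overlap_ratio_pct == 100))
  expect_true(all(m$classification == "neutral"))
  expect_identical(rep1$transform$theta_deg, 0)
  expect_identical(rep1$transform$tx_px, 0)
})

test_that("the evaluation is deterministic and FWHM-convention invariant", {
  tr <- cached("det_triple", simulate_triple(scenario_spec(0, seed = 9)))
  a <- run_evaluation(tr$nonmar, tr$mar, tr$reference, config = small_cfg)
  b <- run_evaluation(tr$nonmar, tr$mar, tr$reference, config = small_cfg)
  expect_identical(as.data.frame(a$metrics), as.data.frame(b$metrics))
  cc <- run_evaluation(tr$nonmar, tr$mar, tr$reference,
                       config = c(small_cfg, list(fwhm_convention = "conventional")))
  expect_equal(
    as.data.frame(a$metrics[, c("fwhm_nm", "fwhm_m", "cent_nm", "cent_m")]),
    as.data.frame(cc$metrics[, c("fwhm_nm", "fwhm_m", "cent_nm", "cent_m")])
  )
})

test_that("near-zone FWHM_NM never decreases along a streak amplitude ladder", {
  base <- scenario_spec(0, seed = 13)
  amps <- base$artifact$amplitude_hu * c(0.4, 0.7, 1, 1.3)
  vals <- vapply(amps, function(a) {
    sp <- base; sp$artifact$amplitude_hu <- a
    tr <- simulate_triple(sp)
    rep1 <- run_evaluation(tr$nonmar, tr$mar, tr$reference, config = small_cfg)
    m <- rep1$metrics
    m$fwhm_nm[m$structure == "tissue" & m$zone == "near"]
  }, numeric(1))
  expect_true(all(diff(vals) >= 0))
})

test_that("tidy, glance and autoplot expose the report tabularly", {
  rep1 <- identity_report()
  td <- generics::tidy(rep1)
  expect_s3_class(td, "tbl_df")
  expect_equal(nrow(td), 6)
  gl <- generics::glance(rep1)
  expect_equal(gl$n_regions, 6)
  expect_equal(gl$mean_overlap_pct, 100)
  p <- ggplot2::autoplot(rep1)
  expect_s3_class(p, "ggplot")
})
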