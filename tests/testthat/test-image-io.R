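test_that("DICOM stored values are rescaled to HU and spacing is read", {
  f <- withr::local_tempfile(fileext = ".dcm")
  stored <- matrix(c(1024L, 0L, 2048L, 1024L, 3024L, 24L), 2, 3)
  build_test_dicom(f, stored, slope = 1, intercept = -1024)
  img <- read_ct_slice(f)
  expect_equal(img$pixels, stored - 1024)
  expect_equal(img$pixels[1, 1], 0)           # 1024 * 1 - 1024
  expect_equal(img$spacing_mm, c(0.39, 0.39)) # clinical pixel size
})

test_that("missing pixel spacing is a hard error, not a silent default", {
  f <- withr::local_tempfile(fileext = ".dcm")
  build_test_dicom(f, matrix(0L, 4, 4), spacing = NULL)
  expect_error(read_ct_slice(f), class = "marref_missing_spacing")

  # NIfTI with pixdim zeroed in the raw header (spacing truly absent)
  f2 <- withr::local_tempfile(fileext = ".nii")
  RNifti::writeNifti(RNifti::asNifti(matrix(0, 8, 8)), f2)
  bytes <- readBin(f2, "raw", file.size(f2))
  bytes[81:88] <- as.raw(0)  # pixdim[1:2] float32 at offset 80
  writeBin(bytes, f2)
  expect_error(read_ct_slice(f2), class = "marref_missing_spacing")
})

test_that("multi-slice volumes are rejected rather than silently sliced", {
  f <- withr::local_tempfile(fileext = ".nii")
  im <- RNifti::asNifti(array(0, dim = c(8, 8, 3)))
  RNifti::pixdim(im) <- c(1, 1, 1)
  RNifti::writeNifti(im, f)
  expect_error(read_ct_slice(f), class = "marref_format")
})

test_that("HU round-trips exactly through both formats for integer values", {
  set.seed(7)
  img <- ct_image(matrix(as.numeric(sample(-1000:3000, 48 * 64, TRUE)), 48, 64),
                  spacing_mm = c(0.39, 0.39))
  fd <- withr::local_tempfile(fileext = ".dcm")
  write_ct_slice(img, fd)
  expect_identical(read_ct_slice(fd)$pixels, img$pixels)

  fn <- withr::local_tempfile(fileext = ".nii")
  write_ct_slice(img, fn)
  back <- read_ct_slice(fn)
  expect_equal(back$pixels, img$pixels)
  expect_equal(back$spacing_mm, img$spacing_mm, tolerance = 1e-6)  # float32 header
})

test_that("non-image files and missing files fail cleanly", {
  f <- withr::local_tempfile(fileext = ".dcm")
  writeLines("not a dicom at all, just text", f)
  expect_error(read_ct_slice(f), class = "marref_format")
  expect_error(read_ct_slice(file.path(tempdir(), "no-such-file.dcm")),
               class = "marref_io")
})

test_that("evaluation reports round-trip through JSON and flatten to long CSV", {
  rep1 <- identity_report()

  fj <- withr::local_tempfile(fileext = ".json")
  write_report(rep1, fj)
  back <- read_report(fj)
  expect_equal(as.data.frame(back$metrics), as.data.frame(rep1$metrics))
  expect_equal(back$transform$theta_deg, rep1$transform$theta_deg)

  fc <- withr::local_tempfile(fileext = ".csv")
  write_report(rep1, fc, format = "csv")
  long <- read.csv(fc)
  # 2 structures x 3 zones x 5 metrics
  expect_equal(nrow(long), 30)
  expect_setequal(unique(long$metric),
                  c("fwhm_nm", "fwhm_m", "cent_nm", "cent_m", "overlap_ratio_pct"))

  expect_error(write_report(rep1, file.path(tempdir(), "nope", "r.json")),
               class = "marref_io")
})

test_that("mask overlays render with window/level and reject shape mismatch", {
  img <- ct_image(matrix(rnorm(32 * 32, 40, 200), 32, 32), c(1, 1))
  msk <- region_mask(matrix(rep(c(TRUE, FALSE), each = 16 * 32), 32, 32), "bone",
                     spacing_mm = c(1, 1))
  f <- withr::local_tempfile(fileext = ".png")
  write_mask_overlay(img, list(msk), f)
  expect_true(file.exists(f) && file.size(f) > 0)
  arr <- png::readPNG(f)
  expect_equal(dim(arr)[1:2], c(32, 32))

  # empty mask list: plain windowed image
  f2 <- withr::local_tempfile(fileext = ".png")
  write_mask_overlay(img, list(), f2)
  expect_true(file.exists(f2))

  bad <- region_mask(matrix(FALSE, 8, 8), "bone", spacing_mm = c(1, 1))
  expect_error(write_mask_overlay(img, list(bad), f),
               class = "marref_shape_mismatch")
})
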