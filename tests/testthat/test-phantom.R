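test_that("the same spec and seed reproduces the triple bit for bit", {
  a <- simulate_triple(small_spec(seed = 21))
  b <- simulate_triple(small_spec(seed = 21))
  expect_identical(a$reference$pixels, b$reference$pixels)
  expect_identical(a$nonmar$pixels, b$nonmar$pixels)
  expect_identical(a$mar$pixels, b$mar$pixels)
  c <- simulate_triple(small_spec(seed = 22))
  expect_false(identical(a$nonmar$pixels, c$nonmar$pixels))
})

test_that("ground-truth masks partition the grid", {
  m <- phantom_masks(small_spec())
  total <- m$air$pixels + m$tissue$pixels + m$bone$pixels + m$metal$pixels
  expect_true(all(total == 1))
})

test_that("without noise every region pixel equals its generating mean", {
  sp <- small_spec(tissue_hu = c(40, 0), bone_hu = c(1000, 0), noise_sd_hu = 0)
  r <- generate_reference(sp)
  expect_true(all(r$image$pixels[r$masks$tissue$pixels] == 40))
  expect_true(all(r$image$pixels[r$masks$bone$pixels] == 1000))
  expect_true(all(r$image$pixels[r$masks$air$pixels] == -1000))
})

test_that("generated tissue noise has the requested first two moments", {
  sp <- phantom_position1(image_size = 256, spacing_mm = 0.6, seed = 31)
  r <- generate_reference(sp)
  v <- r$image$pixels[r$masks$tissue$pixels]
  expect_gt(length(v), 20000)
  expect_lt(abs(mean(v) - 40), 0.5)
  expect_lt(abs(sd(v) / 15 - 1), 0.05)
})

test_that("zero-amplitude artifacts change nothing outside the metal disk", {
  sp <- small_spec(artifact = list(n_streaks = 24, amplitude_hu = 0,
                                   decay_power = 1, dark_band_hu = 0))
  r <- generate_reference(sp)
  nm <- apply_metal_and_artifacts(r$image, sp)
  out <- !r$masks$metal$pixels
  expect_identical(nm$pixels[out], r$image$pixels[out])
  expect_true(all(nm$pixels[r$masks$metal$pixels] == sp$metal$hu))
})

test_that("the streak field is additive-linear in its amplitude", {
  base <- list(n_streaks = 24, amplitude_hu = 50, decay_power = 1, dark_band_hu = 0)
  spA <- small_spec(artifact = base)
  base2 <- base; base2$amplitude_hu <- 100
  spB <- small_spec(artifact = base2)
  r <- generate_reference(spA)
  dA <- apply_metal_and_artifacts(r$image, spA)$pixels - r$image$pixels
  dB <- apply_metal_and_artifacts(r$image, spB)$pixels - r$image$pixels
  out <- !phantom_masks(spA)$metal$pixels
  expect_equal(dB[out], 2 * dA[out], tolerance = 1e-12)
})

test_that("streaks follow the stated angular/radial field formula", {
  amp <- 57
  sp <- small_spec(artifact = list(n_streaks = 24, amplitude_hu = amp,
                                   decay_power = 1.4, dark_band_hu = 0))
  r0 <- generate_reference(sp)
  nm <- apply_metal_and_artifacts(r0$image, sp)
  added <- nm$pixels - r0$image$pixels
  # independent evaluation of amp * cos(n theta + phi) / (1 + r/rm)^p on
  # the pixel-centre mm grid
  n <- sp$image_size; ctr <- (n + 1) / 2
  x <- (matrix(1:n, n, n, byrow = TRUE) - ctr) * sp$spacing_mm - sp$metal$center_mm[1]
  y <- (matrix(1:n, n, n) - ctr) * sp$spacing_mm - sp$metal$center_mm[2]
  r <- sqrt(x^2 + y^2); theta <- atan2(y, x)
  rm_ <- sp$metal$diameter_mm / 2
  phi <- marref:::streak_phase(sp)
  expected <- amp * cos(24 * theta + phi) / (1 + r / rm_)^1.4
  out <- r > rm_
  expect_equal(added[out], expected[out], tolerance = 1e-12)
  # the envelope halves between r = rm and r = 3 rm for decay_power 1
  env <- function(rr, p) 1 / (1 + rr / rm_)^p
  expect_equal(env(rm_, 1) / env(3 * rm_, 1), 2)
})

test_that("the correction emulator honours its blend limits", {
  sp <- scenario_spec(0)
  r <- generate_reference(sp)
  nm <- apply_metal_and_artifacts(r$image, sp)
  metal <- phantom_masks(sp)$metal$pixels

  sp1 <- sp; sp1$mar$residual_fraction <- 1
  expect_identical(apply_mar_emulation(nm, r$image, sp1)$pixels, nm$pixels)

  sp0 <- sp; sp0$mar$residual_fraction <- 0
  m0 <- apply_mar_emulation(nm, r$image, sp0)
  expect_identical(m0$pixels[!metal], r$image$pixels[!metal])
  expect_identical(m0$pixels[metal], nm$pixels[metal])

  sp5 <- sp; sp5$mar$residual_fraction <- 0.5
  m5 <- apply_mar_emulation(nm, r$image, sp5)
  expect_equal(m5$pixels[!metal] - r$image$pixels[!metal],
               0.5 * (nm$pixels[!metal] - r$image$pixels[!metal]),
               tolerance = 1e-12)
})

test_that("misalignment is the registration module's resampler", {
  img <- generate_reference(small_spec())$image
  expect_identical(apply_misalignment(img, rigid_transform(0, 0, 0))$pixels, img$pixels)
  sh <- apply_misalignment(img, rigid_transform(0, 1, 0))
  # integer column shift: interior pixel (r, c) equals source (r, c - 1)
  expect_equal(sh$pixels[20:140, 21:140], img$pixels[20:140, 20:139])
})

test_that("near-zone spread strictly increases with streak amplitude", {
  sds <- vapply(c(20, 40, 60, 80), function(a) {
    sp <- small_spec(seed = 13,
                     artifact = list(n_streaks = 24, amplitude_hu = a,
                                     decay_power = 1, dark_band_hu = 0))
    r <- generate_reference(sp)
    nm <- apply_metal_and_artifacts(r$image, sp)
    g <- marref:::phantom_grids(sp)
    rr <- sqrt((g$x - sp$metal$center_mm[1])^2 + (g$y - sp$metal$center_mm[2])^2)
    sel <- r$masks$tissue$pixels & rr < 20
    sd(nm$pixels[sel])
  }, numeric(1))
  expect_true(all(diff(sds) > 0))
})

test_that("streak calibration hits the requested near-zone sd inflation", {
  sp <- scenario_spec(0)
  r <- generate_reference(sp)
  nm <- apply_metal_and_artifacts(r$image, sp)
  g <- marref:::phantom_grids(sp)
  rr <- sqrt((g$x - sp$metal$center_mm[1])^2 + (g$y - sp$metal$center_mm[2])^2)
  sel <- r$masks$tissue$pixels & rr < 20
  expect_equal(sd(nm$pixels[sel]) / sd(r$image$pixels[sel]), 1.5, tolerance = 0.08)
})

test_that("phantom specs survive a YAML round trip", {
  sp <- small_spec(seed = 77)
  f <- withr::local_tempfile(fileext = ".yaml")
  write_phantom_spec(sp, f)
  sp2 <- read_phantom_spec(f)
  expect_equal(sp2$metal, sp$metal)
  expect_equal(sp2$misalignment$tx_px, sp$misalignment$tx_px)
  expect_identical(generate_reference(sp2)$image$pixels,
                   generate_reference(sp)$image$pixels)
})

test_that("invalid geometry and parameters are rejected", {
  expect_error(small_spec(metal = list(center_mm = c(70, 0), diameter_mm = 8, hu = 8000)),
               class = "marref_bad_geometry")
  expect_error(small_spec(mar = list(residual_fraction = 1.5,
                                     distortion = list(radius_mm = 15, amplitude_hu = 0))),
               class = "marref_bad_input")
  expect_error(small_spec(noise_sd_hu = -1), class = "marref_bad_input")
})
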