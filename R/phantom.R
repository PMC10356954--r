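# Seed hygiene: run `code` under a temporary RNG state so simulation calls
# never disturb the caller's RNG stream.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv(), inherits = FALSE)
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Synthetic phantom specification
#'
#' Describes a lower-extremity-like software phantom: a soft-tissue body
#' ellipse on an air background, circular bone inserts, an 8 mm metal disk,
#' radial streak artifacts decaying with distance from the metal, a
#' partially corrected counterpart with an optional near-metal distortion
#' patch, and a sub-pixel rigid misalignment of the metal-free reference.
#' Geometry is given in mm relative to the image centre, `(x, y)` with x
#' along columns and y along rows.
#'
#' Default geometry follows a clinical knee/tibia protocol: 512 px at
#' 0.39 mm spacing and an 8 mm stainless-steel-like disk at 8000 HU.
#'
#' @param image_size Pixels per side (square image).
#' @param spacing_mm Isotropic pixel size in mm.
#' @param body List: `center_mm` (x, y) and `semi_axes_mm` (x, y) of the
#'   soft-tissue ellipse.
#' @param bones List of disks: each `list(center_mm = c(x, y), radius_mm =, inner_radius_mm = 0)`.
#' @param metal List: `center_mm`, `diameter_mm`, `hu`.
#' @param tissue_hu,bone_hu Length-2 `(mean, sd)` in HU; the sd generates
#'   the in-region pixel noise.
#' @param air_hu Constant background HU.
#' @param artifact List: `n_streaks` (angular frequency), `amplitude_hu`
#'   (peak streak HU at the metal edge), `decay_power` (radial falloff
#'   exponent), `dark_band_hu` (uniform depression within 2 metal radii).
#' @param mar List: `residual_fraction` in `[0, 1]` (how much of the streak
#'   residue survives correction) and `distortion`
#'   (`list(radius_mm =, amplitude_hu =)`, the near-metal patch where the
#'   correction itself perturbs pixel values).
#' @param misalignment A [rigid_transform] applied to the reference slice.
#' @param noise_sd_hu Additional global detector-noise sd in HU.
#' @param noise_corr_px Spatial correlation scale of the pixel noise in
#'   pixels. CT noise is correlated by the reconstruction kernel; white
#'   pixel noise would be an unrealistic worst case for any interpolation
#'   step (resampling would visibly narrow the HU distributions). Set 0 for
#'   white noise.
#' @param seed Integer RNG seed; the same spec + seed is bit-reproducible.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(image_size = 512,
                         spacing_mm = 0.39,
                         body = list(center_mm = c(0, 0), semi_axes_mm = c(70, 88)),
                         bones = list(list(center_mm = c(-22, 0), radius_mm = 16)),
                         metal = list(center_mm = c(0, 8), diameter_mm = 8, hu = 8000),
                         tissue_hu = c(40, 15),
                         bone_hu = c(1000, 100),
                         air_hu = -1000,
                         artifact = list(n_streaks = 24, amplitude_hu = 80,
                                         decay_power = 1, dark_band_hu = 30),
                         mar = list(residual_fraction = 0.5,
                                    distortion = list(radius_mm = 15, amplitude_hu = 0)),
                         misalignment = rigid_transform(0.15, 0.4, -0.3),
                         noise_sd_hu = 0,
                         noise_corr_px = 1,
                         seed = 1) {
  spec <- structure(
    list(image_size = as.integer(image_size), spacing_mm = spacing_mm, body = body,
         bones = bones, metal = metal, tissue_hu = as.numeric(tissue_hu),
         bone_hu = as.numeric(bone_hu), air_hu = air_hu, artifact = artifact,
         mar = mar, misalignment = misalignment, noise_sd_hu = noise_sd_hu,
         noise_corr_px = noise_corr_px, seed = as.integer(seed)),
    class = "phantom_spec"
  )
  validate_phantom_spec(spec)
}

validate_phantom_spec <- function(spec) {
  half_fov <- spec$image_size * spec$spacing_mm / 2
  b <- spec$body
  if (any(abs(b$center_mm) + b$semi_axes_mm > half_fov)) {
    mar_abort("body ellipse extends outside the image bounds", "bad_geometry")
  }
  m <- spec$metal
  if (m$diameter_mm <= 0) mar_abort("metal diameter must be positive", "bad_geometry")
  # metal strictly inside the body ellipse (conservative circumscribed check)
  r <- m$diameter_mm / 2
  d <- m$center_mm - b$center_mm
  if (sum(((abs(d) + r) / b$semi_axes_mm)^2) >= 1) {
    mar_abort("metal disk must lie strictly inside the body", "bad_geometry")
  }
  rf <- spec$mar$residual_fraction
  if (rf < 0 || rf > 1) mar_abort("residual_fraction must be in [0, 1]", "bad_input")
  if (spec$noise_sd_hu < 0) mar_abort("noise_sd_hu must be >= 0", "bad_input")
  if (spec$tissue_hu[2] < 0 || spec$bone_hu[2] < 0) {
    mar_abort("HU standard deviations must be >= 0", "bad_input")
  }
  spec
}

# Raw generating geometry (no metal exclusion): body ellipse and bone disks.
phantom_geometry <- function(spec) {
  g <- phantom_grids(spec)
  b <- spec$body
  body <- ((g$x - b$center_mm[1]) / b$semi_axes_mm[1])^2 +
    ((g$y - b$center_mm[2]) / b$semi_axes_mm[2])^2 <= 1
  bone <- matrix(FALSE, spec$image_size, spec$image_size)
  for (bn in spec$bones) {
    r2 <- (g$x - bn$center_mm[1])^2 + (g$y - bn$center_mm[2])^2
    disk <- r2 <= bn$radius_mm^2
    inner <- bn$inner_radius_mm %||% 0
    if (inner > 0) disk <- disk & r2 >= inner^2
    bone <- bone | disk
  }
  metal <- (g$x - spec$metal$center_mm[1])^2 + (g$y - spec$metal$center_mm[2])^2 <=
    (spec$metal$diameter_mm / 2)^2
  list(body = body, bone = bone & body, metal = metal)
}

# mm coordinate grids (pixel centres) relative to the image centre.
phantom_grids <- function(spec) {
  n <- spec$image_size
  ctr <- (n + 1) / 2
  x <- (matrix(seq_len(n), n, n, byrow = TRUE) - ctr) * spec$spacing_mm
  y <- (matrix(seq_len(n), n, n) - ctr) * spec$spacing_mm
  list(x = x, y = y)
}

#' Ground-truth masks of a phantom spec
#'
#' The four structure masks defined directly by the generating geometry.
#' They partition the grid: air, tissue, bone and metal are pairwise
#' disjoint and their union covers every pixel (the metal mask is the disk
#' geometry; in the metal-free reference those pixels hold tissue/bone
#' values but are still reported under `metal` so the partition is stable
#' across the triple).
#'
#' @param spec A [phantom_spec].
#' @return Named list of [region_mask]: `air`, `tissue`, `bone`, `metal`.
#' @export
phantom_masks <- function(spec) {
  geo <- phantom_geometry(spec)
  sp <- rep(spec$spacing_mm, 2)
  list(
    air = region_mask(!geo$body, "air", spacing_mm = sp),
    tissue = region_mask(geo$body & !geo$bone & !geo$metal, "tissue", spacing_mm = sp),
    bone = region_mask(geo$bone & !geo$metal, "bone", spacing_mm = sp),
    metal = region_mask(geo$metal, "metal", spacing_mm = sp)
  )
}

#' Generate the metal-free reference slice
#'
#' Air background, body ellipse at the tissue HU, bone disks at the bone HU,
#' with per-region Gaussian pixel noise (the region sds) plus optional
#' global detector noise. No metal is present; the returned masks are the
#' exact generating geometry.
#'
#' @param spec A [phantom_spec].
#' @return List with `image` (a [ct_image]) and `masks` (see
#'   [phantom_masks()]).
#' @export
generate_reference <- function(spec) {
  masks <- phantom_masks(spec)
  geo <- phantom_geometry(spec)
  n <- spec$image_size
  px <- matrix(spec$air_hu, n, n)
  # underlying material, independent of where the metal will sit
  tissue_region <- geo$body & !geo$bone
  bone_region <- geo$bone
  corr <- spec$noise_corr_px %||% 0
  with_seed(spec$seed, {
    px[tissue_region] <- spec$tissue_hu[1]
    px[bone_region] <- spec$bone_hu[1]
    if (spec$tissue_hu[2] > 0 || spec$bone_hu[2] > 0) {
      noise <- unit_noise_field(n, corr)   # pixelwise unit variance
      px[tissue_region] <- px[tissue_region] + spec$tissue_hu[2] * noise[tissue_region]
      px[bone_region] <- px[bone_region] + spec$bone_hu[2] * noise[bone_region]
    }
    if (spec$noise_sd_hu > 0) px <- px + spec$noise_sd_hu * unit_noise_field(n, corr)
  })
  img <- ct_image(px, rep(spec$spacing_mm, 2),
                  origin_tag = sprintf("phantom-reference(seed=%d)", spec$seed))
  list(image = img, masks = masks)
}

# Streak phase is a deterministic function of the spec seed.
streak_phase <- function(spec) with_seed(spec$seed + 1000003L, runif(1, 0, 2 * pi))

# Unit-amplitude streak field (amplitude_hu = 1, dark band excluded);
# zero inside the metal disk.
streak_field_unit <- function(spec) {
  g <- phantom_grids(spec)
  mx <- spec$metal$center_mm[1]; my <- spec$metal$center_mm[2]
  r <- sqrt((g$x - mx)^2 + (g$y - my)^2)
  theta <- atan2(g$y - my, g$x - mx)
  rm_ <- spec$metal$diameter_mm / 2
  phi <- streak_phase(spec)
  a <- spec$artifact
  s <- cos(a$n_streaks * theta + phi) / (1 + r / rm_)^a$decay_power
  s[r <= rm_] <- 0
  s
}

#' Insert metal and streak artifacts into a reference slice
#'
#' Metal-disk pixels are set to the metal HU; an additive angular streak
#' field `amplitude * cos(n_streaks * theta + phi) / (1 + r/r_metal)^decay`
#' is applied outside the metal, and a uniform dark band of `dark_band_hu`
#' is subtracted within two metal radii (the photon-starvation dark field).
#' The streak phase `phi` is drawn once from the seeded RNG.
#'
#' @param reference The `image` from [generate_reference()] (same spec).
#' @param spec The [phantom_spec].
#' @return The uncorrected metal-bearing [ct_image].
#' @export
apply_metal_and_artifacts <- function(reference, spec) {
  g <- phantom_grids(spec)
  mx <- spec$metal$center_mm[1]; my <- spec$metal$center_mm[2]
  r <- sqrt((g$x - mx)^2 + (g$y - my)^2)
  rm_ <- spec$metal$diameter_mm / 2
  px <- reference$pixels + spec$artifact$amplitude_hu * streak_field_unit(spec)
  band <- r > rm_ & r <= 2 * rm_
  px[band] <- px[band] - spec$artifact$dark_band_hu
  px[r <= rm_] <- spec$metal$hu
  ct_image(px, reference$spacing_mm,
           origin_tag = sprintf("phantom-nonmar(seed=%d)", spec$seed))
}

# Gaussian-correlated noise field with exactly unit pixelwise variance:
# white noise smoothed at scale `corr_px` and rescaled by the kernel's
# theoretical sd reduction factor (sum of squared separable weights).
unit_noise_field <- function(n, corr_px) {
  w <- matrix(rnorm(n * n), n, n)
  if (corr_px <= 0) return(w)
  R <- max(1L, ceiling(3 * corr_px))
  k <- stats::dnorm(-R:R, sd = corr_px)
  k <- k / sum(k)
  gauss_smooth(w, corr_px) / sum(k^2)  # separable: pixel var = (sum k^2)^2
}

# Band-limited, seeded noise field standardized over `sel` (mean 0, sd 1).
bandlimited_field <- function(n, seed, sel, smooth_sigma = 2) {
  w <- with_seed(seed, matrix(rnorm(n * n), n, n))
  f <- gauss_smooth(w, smooth_sigma)
  mu <- mean(f[sel]); sd_ <- stats::sd(f[sel])
  (f - mu) / sd_
}

#' Emulate a metal-artifact-reduction result
#'
#' Outside the distortion patch the correction blends the streak residue:
#' `mar = reference + residual_fraction * (nonmar - reference)`. Inside the
#' patch (a disk around the metal centre, metal excluded) an additional
#' zero-mean band-limited perturbation scaled by the distortion amplitude is
#' added, emulating the restoration failure close to the metal. Metal pixels
#' are copied from the uncorrected image.
#'
#' @param nonmar,reference [ct_image]s from the same spec.
#' @param spec The [phantom_spec].
#' @return The corrected [ct_image].
#' @export
apply_mar_emulation <- function(nonmar, reference, spec) {
  check_same_grid(nonmar, reference)
  g <- phantom_grids(spec)
  mx <- spec$metal$center_mm[1]; my <- spec$metal$center_mm[2]
  r <- sqrt((g$x - mx)^2 + (g$y - my)^2)
  rm_ <- spec$metal$diameter_mm / 2
  metal <- r <= rm_
  px <- reference$pixels + spec$mar$residual_fraction * (nonmar$pixels - reference$pixels)
  dist <- spec$mar$distortion
  if ((dist$amplitude_hu %||% 0) > 0) {
    patch <- r <= dist$radius_mm & !metal
    f <- bandlimited_field(spec$image_size, spec$seed + 2000003L, patch)
    px[patch] <- px[patch] + dist$amplitude_hu * f[patch]
  }
  px[metal] <- nonmar$pixels[metal]
  ct_image(px, nonmar$spacing_mm,
           origin_tag = sprintf("phantom-mar(seed=%d)", spec$seed))
}

#' Misalign a slice by a rigid transform
#'
#' Emulates the small table/gantry position change between the evaluation
#' scan and the reference scan by resampling through the registration
#' module's bilinear resampler (identical interpolation contract).
#'
#' @param image A [ct_image].
#' @param transform A [rigid_transform].
#' @param fill_hu Fill value outside the domain.
#' @return The misaligned [ct_image].
#' @export
apply_misalignment <- function(image, transform, fill_hu = -1000) {
  resample_rigid(image, transform, fill_hu = fill_hu)
}

#' Simulate a matched (reference, non-MAR, MAR) slice triple
#'
#' Runs the full generator: reference slice, metal + streak insertion,
#' correction emulation, and rigid misalignment of the reference. The
#' returned `reference` is the misaligned slice (what a second scan would
#' deliver); `reference_aligned` is the pre-misalignment slice for oracle
#' comparisons.
#'
#' @param spec A [phantom_spec].
#' @return List: `reference`, `reference_aligned`, `nonmar`, `mar`,
#'   `masks`, `spec`.
#' @export
simulate_triple <- function(spec) {
  ref <- generate_reference(spec)
  nonmar <- apply_metal_and_artifacts(ref$image, spec)
  mar <- apply_mar_emulation(nonmar, ref$image, spec)
  reference <- apply_misalignment(ref$image, spec$misalignment, fill_hu = spec$air_hu)
  list(reference = reference, reference_aligned = ref$image,
       nonmar = nonmar, mar = mar, masks = ref$masks, spec = spec)
}

#' Calibrate the streak amplitude for a target near-zone sd inflation
#'
#' Computes, from the generating model, the streak `amplitude_hu` for which
#' the uncorrected image's near-zone tissue HU standard deviation is
#' inflated by `target_inflation` relative to the reference:
#' `amplitude = sd_ref * sqrt(target^2 - 1) / rms`, where `rms` is the
#' root-mean-square of the unit-amplitude streak field over near-zone
#' tissue pixels and `sd_ref` the empirical near-zone sd of the (seeded,
#' hence deterministic) reference slice. Deterministic for a given spec.
#'
#' @param spec A [phantom_spec].
#' @param target_inflation Desired near-zone sd ratio (> 1).
#' @param near_radius_mm Near-zone radius around the metal centre.
#' @return The calibrated amplitude in HU.
#' @export
calibrate_streak_amplitude <- function(spec, target_inflation = 1.5, near_radius_mm = 20) {
  if (target_inflation <= 1) mar_abort("target_inflation must exceed 1", "bad_input")
  ref <- generate_reference(spec)
  g <- phantom_grids(spec)
  r <- sqrt((g$x - spec$metal$center_mm[1])^2 + (g$y - spec$metal$center_mm[2])^2)
  sel <- ref$masks$tissue$pixels & r < near_radius_mm & r > spec$metal$diameter_mm / 2
  if (!any(sel)) mar_abort("no near-zone tissue pixels to calibrate on", "empty_region")
  rms <- sqrt(mean(streak_field_unit(spec)[sel]^2))
  sd_ref <- stats::sd(ref$image$pixels[sel])
  if (sd_ref <= 0) mar_abort("reference near zone has zero variance", "bad_input")
  sd_ref * sqrt(target_inflation^2 - 1) / rms
}

#' Canonical phantom presets
#'
#' Two geometries mirroring the two analysed configurations of a
#' metal-in-tibia phantom experiment: position 1 has the metal in soft
#' tissue with part of the tibia inside the 20 mm near zone; position 2 has
#' the metal inside the tibia with tissue outside the bone. Geometry is in
#' mm, so the same preset can be rendered at reduced resolution by lowering
#' `image_size` and raising `spacing_mm`.
#'
#' @param image_size,spacing_mm Grid geometry (defaults: 512 px, 0.39 mm).
#' @param ... Further arguments passed to [phantom_spec()].
#' @return A [phantom_spec].
#' @export
phantom_position1 <- function(image_size = 512, spacing_mm = 0.39, ...) {
  args <- list(
    image_size = image_size, spacing_mm = spacing_mm,
    body = list(center_mm = c(0, 0), semi_axes_mm = c(55, 70)),
    bones = list(list(center_mm = c(-24, -2), radius_mm = 15),
                 list(center_mm = c(32, 24), radius_mm = 7)),
    metal = list(center_mm = c(0, 6), diameter_mm = 8, hu = 8000)
  )
  do.call(phantom_spec, modifyList(args, list(...)))
}

#' @rdname phantom_position1
#' @export
phantom_position2 <- function(image_size = 512, spacing_mm = 0.39, ...) {
  args <- list(
    image_size = image_size, spacing_mm = spacing_mm,
    body = list(center_mm = c(0, 0), semi_axes_mm = c(55, 70)),
    bones = list(list(center_mm = c(-18, 0), radius_mm = 16),
                 list(center_mm = c(32, 24), radius_mm = 7)),
    metal = list(center_mm = c(-18, 0), diameter_mm = 8, hu = 8000)
  )
  do.call(phantom_spec, modifyList(args, list(...)))
}

#' Read or write a phantom spec as YAML
#'
#' @param spec A [phantom_spec].
#' @param path YAML file path.
#' @return `write_phantom_spec` returns the path invisibly;
#'   `read_phantom_spec` returns a [phantom_spec].
#' @export
write_phantom_spec <- function(spec, path) {
  x <- unclass(spec)
  x$misalignment <- unclass(x$misalignment)
  yaml::write_yaml(x, path)
  invisible(path)
}

#' @rdname write_phantom_spec
#' @export
read_phantom_spec <- function(path) {
  x <- yaml::read_yaml(path)
  x$misalignment <- do.call(rigid_transform, x$misalignment)
  do.call(phantom_spec, x)
}
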