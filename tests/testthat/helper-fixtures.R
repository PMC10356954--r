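# Shared fixtures, computed once per test run and cached.
.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, .fixture_cache)) assign(key, force(expr), .fixture_cache)
  get(key, .fixture_cache)
}

# Reduced-resolution phantom: same mm geometry as the presets, 160 px at
# 1 mm spacing; min_label_px scaled to the ~50 px metal area.
small_spec <- function(seed = 11, ...) {
  phantom_position1(image_size = 160, spacing_mm = 1.0, seed = seed, ...)
}
small_cfg <- list(min_label_px = 30)

# Noiseless phantom at 256 px / 0.6 mm for segmentation fidelity checks.
noiseless_seg_fixture <- function() {
  cached("noiseless_seg", {
    sp <- phantom_position1(
      image_size = 256, spacing_mm = 0.6, seed = 3,
      tissue_hu = c(40, 0), bone_hu = c(1000, 0), noise_sd_hu = 0
    )
    ref <- generate_reference(sp)
    img <- apply_metal_and_artifacts(ref$image, sp)
    metal <- segment_metal(img, min_label_px = 80)
    seg <- segment_structures(img, metal, config = list(min_label_px = 80))
    list(spec = sp, ref = ref, img = img, metal = metal, seg = seg)
  })
}

# Calibrated streak scenario: near-zone tissue sd inflated x1.5, half the
# streak residue surviving correction; optional near-metal distortion patch.
scenario_spec <- function(dist_amp = 0, seed = 5) {
  sp <- phantom_position1(
    image_size = 160, spacing_mm = 1.0, seed = seed,
    artifact = list(n_streaks = 24, amplitude_hu = 1, decay_power = 1, dark_band_hu = 0),
    mar = list(residual_fraction = 0.5,
               distortion = list(radius_mm = 18, amplitude_hu = dist_amp))
  )
  sp$artifact$amplitude_hu <- calibrate_streak_amplitude(sp, 1.5)
  sp
}

scenario_report <- function(dist_amp = 0) {
  cached(paste0("scenario_report_", dist_amp), {
    tr <- simulate_triple(scenario_spec(dist_amp))
    run_evaluation(tr$nonmar, tr$mar, tr$reference, config = small_cfg)
  })
}

identity_report <- function() {
  cached("identity_report", {
    tr <- simulate_triple(small_spec())
    img <- tr$nonmar
    run_evaluation(img, img, img, config = small_cfg)
  })
}

# --- independent minimal DICOM builder (explicit VR little endian) ---------
# Written directly from the encoding rules so reader tests do not depend on
# the package's own writer.
dcm_u16 <- function(v) writeBin(as.integer(v), raw(), size = 2, endian = "little")
dcm_el <- function(group, elem, vr, val) {
  if (length(val) %% 2 == 1) val <- c(val, as.raw(32))
  c(dcm_u16(group), dcm_u16(elem), charToRaw(vr),
    if (vr %in% c("OB", "OW")) c(as.raw(c(0, 0)), writeBin(length(val), raw(), size = 4, endian = "little"))
    else dcm_u16(length(val)),
    val)
}
dcm_str <- function(group, elem, vr, s) dcm_el(group, elem, vr, charToRaw(s))

build_test_dicom <- function(path, stored, slope = 1, intercept = -1024,
                             spacing = "0.39\\0.39", signed = FALSE) {
  stopifnot(is.matrix(stored))
  body <- c(
    dcm_el(0x0028, 0x0010, "US", dcm_u16(nrow(stored))),
    dcm_el(0x0028, 0x0011, "US", dcm_u16(ncol(stored))),
    if (!is.null(spacing)) dcm_str(0x0028, 0x0030, "DS", spacing),
    dcm_el(0x0028, 0x0100, "US", dcm_u16(16)),
    dcm_el(0x0028, 0x0103, "US", dcm_u16(if (signed) 1 else 0)),
    dcm_str(0x0028, 0x1052, "DS", format(intercept)),
    dcm_str(0x0028, 0x1053, "DS", format(slope)),
    dcm_el(0x7FE0, 0x0010, "OW",
           writeBin(as.integer(t(stored)), raw(), size = 2, endian = "little"))
  )
  meta <- dcm_str(0x0002, 0x0010, "UI", "1.2.840.10008.1.2.1")
  writeBin(c(raw(128), charToRaw("DICM"), meta, body), path)
  path
}
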