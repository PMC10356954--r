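# --- minimal single-frame DICOM codec -------------------------------------
#
# Only what a single-slice CT export needs: little-endian explicit or
# implicit VR, uncompressed 16-bit pixel data, the geometry/rescale tags.
# Sequences with undefined length and compressed transfer syntaxes are
# rejected rather than guessed at.

DICOM_EXPLICIT_LE <- "1.2.840.10008.1.2.1"
DICOM_IMPLICIT_LE <- "1.2.840.10008.1.2"

read_uint16 <- function(raw) readBin(raw, "integer", size = 2, endian = "little", signed = FALSE)
read_uint32 <- function(raw) {
  lo <- read_uint16(raw[1:2]); hi <- read_uint16(raw[3:4])
  lo + hi * 65536
}

parse_dicom_elements <- function(bytes, offset, explicit, stop_group = NULL) {
  out <- list()
  n <- length(bytes)
  long_vrs <- c("OB", "OW", "OF", "SQ", "UT", "UN")
  while (offset + 8 <= n + 1 && offset < n) {
    group <- read_uint16(bytes[offset + 0:1])
    elem  <- read_uint16(bytes[offset + 2:3])
    if (!is.null(stop_group) && group != stop_group) break
    if (explicit || group == 2L) {
      vr <- rawToChar(bytes[offset + 4:5])
      if (vr %in% long_vrs) {
        len <- read_uint32(bytes[offset + 8:11]); hdr <- 12L
      } else {
        len <- read_uint16(bytes[offset + 6:7]); hdr <- 8L
      }
    } else {
      vr <- NA_character_
      len <- read_uint32(bytes[offset + 4:7]); hdr <- 8L
    }
    if (len == 4294967295) {
      mar_abort("DICOM elements with undefined length (sequences) are not supported", "format")
    }
    val_start <- offset + hdr
    if (val_start + len - 1 > n) {
      mar_abort("truncated DICOM element", "format")
    }
    key <- sprintf("%04x,%04x", group, elem)
    out[[key]] <- bytes[seq.int(val_start, length.out = len)]
    offset <- val_start + len
  }
  list(elements = out, offset = offset)
}

dicom_string <- function(el, key) {
  v <- el[[key]]
  if (is.null(v)) return(NULL)
  trimws(rawToChar(v[v != as.raw(0)]))
}

dicom_us <- function(el, key) {
  v <- el[[key]]
  if (is.null(v)) return(NULL)
  read_uint16(v[1:2])
}

read_dicom_slice <- function(path) {
  bytes <- readBin(path, "raw", n = file.size(path))
  if (length(bytes) < 132 || rawToChar(bytes[129:132]) != "DICM") {
    mar_abort(sprintf("'%s' is not a DICOM file (missing DICM marker)", path), "format")
  }
  meta <- parse_dicom_elements(bytes, 133L, explicit = TRUE, stop_group = 2L)
  ts <- dicom_string(meta$elements, "0002,0010") %||% DICOM_EXPLICIT_LE
  if (!ts %in% c(DICOM_EXPLICIT_LE, DICOM_IMPLICIT_LE)) {
    mar_abort(sprintf("unsupported DICOM transfer syntax '%s'", ts), "format")
  }
  ds <- parse_dicom_elements(bytes, meta$offset, explicit = (ts == DICOM_EXPLICIT_LE))$elements

  nframes <- suppressWarnings(as.integer(dicom_string(ds, "0028,0008") %||% "1"))
  if (isTRUE(nframes > 1)) {
    mar_abort("multi-frame DICOM not supported; supply a single axial slice", "format")
  }
  rows <- dicom_us(ds, "0028,0010"); cols <- dicom_us(ds, "0028,0011")
  if (is.null(rows) || is.null(cols)) mar_abort("DICOM lacks Rows/Columns", "format")
  bits <- dicom_us(ds, "0028,0100") %||% 16L
  if (bits != 16L) mar_abort("only 16-bit DICOM pixel data supported", "format")
  signed <- (dicom_us(ds, "0028,0103") %||% 0L) == 1L

  spacing_str <- dicom_string(ds, "0028,0030")
  if (is.null(spacing_str) || spacing_str == "") {
    mar_abort("DICOM lacks PixelSpacing; spacing is required for mm-based analysis",
              "missing_spacing")
  }
  spacing <- as.numeric(strsplit(spacing_str, "\\\\")[[1]])
  if (length(spacing) != 2 || any(!is.finite(spacing)) || any(spacing <= 0)) {
    mar_abort("DICOM PixelSpacing is malformed", "missing_spacing")
  }

  slope <- as.numeric(dicom_string(ds, "0028,1053") %||% "1")
  intercept <- as.numeric(dicom_string(ds, "0028,1052") %||% "0")
  pix_raw <- ds[["7fe0,0010"]]
  if (is.null(pix_raw)) mar_abort("DICOM lacks PixelData", "format")
  if (length(pix_raw) < 2 * rows * cols) mar_abort("DICOM PixelData truncated", "format")
  stored <- readBin(pix_raw, "integer", n = rows * cols, size = 2,
                    endian = "little", signed = signed)
  if (!signed) stored <- as.numeric(stored)  # readBin unsigned already >= 0
  hu <- slope * as.numeric(stored) + intercept
  # DICOM pixel data is row-major: first row left to right.
  pixels <- matrix(hu, nrow = rows, ncol = cols, byrow = TRUE)
  ct_image(pixels, spacing_mm = spacing, origin_tag = path)
}

# Encode one data element (explicit VR little endian).
dicom_element <- function(group, elem, vr, value_raw) {
  if (length(value_raw) %% 2 == 1) value_raw <- c(value_raw, as.raw(if (vr == "UI") 0 else 32))
  head <- c(writeBin(as.integer(group), raw(), size = 2, endian = "little"),
            writeBin(as.integer(elem), raw(), size = 2, endian = "little"),
            charToRaw(vr))
  if (vr %in% c("OB", "OW")) {
    c(head, as.raw(c(0, 0)),
      writeBin(as.integer(length(value_raw)), raw(), size = 4, endian = "little"),
      value_raw)
  } else {
    c(head, writeBin(as.integer(length(value_raw)), raw(), size = 2, endian = "little"),
      value_raw)
  }
}

dicom_str_el <- function(group, elem, vr, s) dicom_element(group, elem, vr, charToRaw(s))
dicom_us_el <- function(group, elem, v) {
  dicom_element(group, elem, "US", writeBin(as.integer(v), raw(), size = 2, endian = "little"))
}

write_dicom_slice <- function(image, path) {
  px <- image$pixels
  stored <- round(px)  # slope 1, intercept 0
  if (any(stored < -32768 | stored > 32767)) {
    mar_abort("HU values outside int16 range cannot be stored", "io")
  }
  body <- c(
    dicom_str_el(0x0008, 0x0060, "CS", "CT"),
    dicom_us_el(0x0028, 0x0010, nrow(px)),
    dicom_us_el(0x0028, 0x0011, ncol(px)),
    dicom_str_el(0x0028, 0x0030, "DS",
                 sprintf("%.6g\\%.6g", image$spacing_mm[1], image$spacing_mm[2])),
    dicom_us_el(0x0028, 0x0100, 16), # BitsAllocated
    dicom_us_el(0x0028, 0x0101, 16), # BitsStored
    dicom_us_el(0x0028, 0x0102, 15), # HighBit
    dicom_us_el(0x0028, 0x0103, 1),  # signed
    dicom_str_el(0x0028, 0x1052, "DS", "0"),
    dicom_str_el(0x0028, 0x1053, "DS", "1"),
    dicom_element(0x7FE0, 0x0010, "OW",
                  writeBin(as.integer(t(stored)), raw(), size = 2, endian = "little"))
  )
  meta <- dicom_str_el(0x0002, 0x0010, "UI", DICOM_EXPLICIT_LE)
  con <- tryCatch(file(path, "wb"), condition = function(e) {
    mar_abort(sprintf("cannot open '%s' for writing", path), "io")
  })
  on.exit(close(con))
  writeBin(c(raw(128), charToRaw("DICM"), meta, body), con)
  invisible(path)
}

# --- public readers ---------------------------------------------------------

#' Read a single CT slice into HU space
#'
#' Reads one axial CT slice from DICOM or NIfTI. DICOM stored values are
#' rescaled to Hounsfield units with RescaleSlope/RescaleIntercept, and pixel
#' spacing is taken from the file metadata. Multi-slice volumes are rejected:
#' the evaluation operates on individual axial slices, and silently taking
#' the first slice of a volume would hide a user error.
#'
#' @param path Path to the image file.
#' @param format_hint `"auto"` (default, from file extension/magic),
#'   `"dicom"`, or `"nifti"`.
#' @return A [ct_image].
#' @export
read_ct_slice <- function(path, format_hint = c("auto", "dicom", "nifti")) {
  format_hint <- match.arg(format_hint)
  if (!file.exists(path)) mar_abort(sprintf("file '%s' does not exist", path), "io")
  fmt <- format_hint
  if (fmt == "auto") {
    lower <- tolower(path)
    fmt <- if (grepl("\\.nii(\\.gz)?$", lower)) "nifti" else "dicom"
  }
  if (fmt == "dicom") read_dicom_slice(path) else read_nifti_slice(path)
}

# Raw NIfTI-1 header peek: RNifti sanitises nonpositive pixdim to 1 on
# read, which would silently hide missing spacing, so inspect the header
# bytes directly (dim at offset 40: 8 x int16; pixdim at 76: 8 x float32).
nifti_header_pixdim <- function(path) {
  con <- gzfile(path, "rb")
  on.exit(close(con))
  hdr <- readBin(con, "raw", n = 348)
  if (length(hdr) < 348) return(NULL)
  sizeof_hdr <- readBin(hdr[1:4], "integer", size = 4, endian = "little")
  if (sizeof_hdr != 348) return(NULL)  # not NIfTI-1; fall back to RNifti
  ndim <- readBin(hdr[41:42], "integer", size = 2, endian = "little")
  pixdim <- readBin(hdr[77:112], "numeric", n = 8, size = 4, endian = "little")
  list(ndim = ndim, pixdim = pixdim[-1])
}

read_nifti_slice <- function(path) {
  hdr <- nifti_header_pixdim(path)
  img <- tryCatch(RNifti::readNifti(path), error = function(e) {
    mar_abort(sprintf("cannot read NIfTI '%s': %s", path, conditionMessage(e)), "format")
  })
  d <- dim(img)
  d_eff <- d[d > 1]
  if (length(d_eff) > 2) {
    mar_abort("NIfTI volume has more than one slice; supply a single 2D slice", "format")
  }
  pd <- RNifti::pixdim(img)[seq_along(d)][d > 1]
  if (!is.null(hdr)) {
    pd_raw <- hdr$pixdim[seq_along(d)][d > 1]
    if (any(!is.finite(pd_raw)) || any(pd_raw <= 0)) {
      mar_abort("NIfTI lacks usable pixel spacing (pixdim <= 0)", "missing_spacing")
    }
  }
  if (length(pd) != 2 || any(!is.finite(pd)) || any(pd <= 0)) {
    mar_abort("NIfTI lacks usable pixel spacing (pixdim <= 0)", "missing_spacing")
  }
  px <- array(as.numeric(img), dim = d)
  px <- matrix(px, nrow = d_eff[1], ncol = d_eff[2])
  ct_image(px, spacing_mm = pd, origin_tag = path)
}

#' Write a CT slice
#'
#' Counterpart of [read_ct_slice()] used for exporting simulated slices and
#' for lossless round-trips (HU values are stored as integers; the affine
#' stored-value/HU conversion is exactly invertible for integer HU).
#'
#' @param image A [ct_image].
#' @param path Output path; format from extension unless `format` given.
#' @param format `"auto"`, `"dicom"` or `"nifti"`.
#' @return The path, invisibly.
#' @export
write_ct_slice <- function(image, path, format = c("auto", "dicom", "nifti")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.nii(\\.gz)?$", tolower(path))) "nifti" else "dicom"
  }
  if (!dir.exists(dirname(path))) {
    mar_abort(sprintf("directory '%s' does not exist", dirname(path)), "io")
  }
  if (format == "dicom") {
    write_dicom_slice(image, path)
  } else {
    im <- RNifti::asNifti(image$pixels)
    RNifti::pixdim(im) <- image$spacing_mm
    RNifti::writeNifti(im, path)
  }
  invisible(path)
}

# --- evaluation report IO ---------------------------------------------------

report_metric_cols <- c("fwhm_nm", "fwhm_m", "cent_nm", "cent_m", "overlap_ratio_pct")

check_report_complete <- function(report) {
  m <- report$metrics
  need <- expand.grid(structure = unique(m$structure), zone = unique(m$zone),
                      stringsAsFactors = FALSE)
  have <- paste(m$structure, m$zone)
  if (!all(paste(need$structure, need$zone) %in% have)) {
    mar_abort("report is incomplete: missing (structure, zone) combinations", "bad_input")
  }
  invisible(TRUE)
}

#' Write an evaluation report to JSON or CSV
#'
#' JSON serialisation round-trips losslessly through [read_report()]. The CSV
#' form is long format for downstream statistics: one row per
#' (structure, zone, metric).
#'
#' @param report A `mar_report` from [run_evaluation()].
#' @param path Output path.
#' @param format `"json"` or `"csv"`.
#' @return The path, invisibly.
#' @export
write_report <- function(report, path, format = c("json", "csv")) {
  format <- match.arg(format)
  if (!inherits(report, "mar_report")) mar_abort("`report` must be a mar_report", "bad_input")
  check_report_complete(report)
  if (!dir.exists(dirname(path))) {
    mar_abort(sprintf("directory '%s' does not exist", dirname(path)), "io")
  }
  if (format == "json") {
    payload <- list(
      schema = "marref-report/1",
      metrics = report$metrics,
      models = report$models,
      transform = unclass(report$transform),
      config = report$config,
      provenance = report$provenance
    )
    jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA, null = "null")
  } else {
    long <- tidyr::pivot_longer(
      dplyr::select(report$metrics, dplyr::all_of(c("structure", "zone", report_metric_cols))),
      cols = dplyr::all_of(report_metric_cols),
      names_to = "metric", values_to = "value"
    )
    write.csv(long, path, row.names = FALSE)
  }
  invisible(path)
}

#' Read a JSON evaluation report
#'
#' @param path Path written by [write_report()] with `format = "json"`.
#' @return A `mar_report`.
#' @export
read_report <- function(path) {
  if (!file.exists(path)) mar_abort(sprintf("file '%s' does not exist", path), "io")
  payload <- jsonlite::read_json(path, simplifyVector = TRUE)
  new_mar_report(
    metrics = tibble::as_tibble(payload$metrics),
    models = tibble::as_tibble(payload$models),
    transform = do.call(rigid_transform, payload$transform[c("theta_deg", "tx_px", "ty_px")]),
    config = payload$config,
    provenance = payload$provenance
  )
}

# --- overlay rendering ------------------------------------------------------

overlay_palette <- c(metal = "#e41a1c", bone = "#ffd92f", tissue = "#4daf4a",
                     air = "#377eb8", body = "#984ea3")

#' Render a slice with mask overlays to PNG
#'
#' The HU background is displayed through a window/level ramp (default
#' 400/40, the soft-tissue window); each mask is blended on top in a
#' distinct colour per structure.
#'
#' @param image A [ct_image].
#' @param masks List of [region_mask] objects sharing the image grid.
#' @param path Output PNG path.
#' @param window,level Display window width and centre in HU.
#' @param alpha Overlay opacity in `[0, 1]`.
#' @return The path, invisibly.
#' @export
write_mask_overlay <- function(image, masks = list(), path, window = 400, level = 40,
                               alpha = 0.4) {
  if (inherits(masks, "region_mask")) masks <- list(masks)
  px <- image$pixels
  for (m in masks) {
    if (!identical(dim(m$pixels), dim(px))) {
      mar_abort("mask shape does not match image", "shape_mismatch")
    }
  }
  if (!dir.exists(dirname(path))) {
    mar_abort(sprintf("directory '%s' does not exist", dirname(path)), "io")
  }
  g <- pmin(pmax((px - (level - window / 2)) / window, 0), 1)
  rgb_arr <- array(g, dim = c(nrow(px), ncol(px), 3))
  for (m in masks) {
    col <- grDevices::col2rgb(overlay_palette[[m$structure]] %||% "#ff00ff") / 255
    sel <- m$pixels
    for (k in 1:3) {
      ch <- rgb_arr[, , k]
      ch[sel] <- (1 - alpha) * ch[sel] + alpha * col[k]
      rgb_arr[, , k] <- ch
    }
  }
  png::writePNG(rgb_arr, path)
  invisible(path)
}
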