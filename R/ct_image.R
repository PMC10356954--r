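#' @importFrom rlang %||%
#' @importFrom stats optim rnorm runif setNames
#' @importFrom utils head tail modifyList write.csv read.csv
NULL

# Classed condition helper: every error carries c("marref_<class>", "marref_error").
mar_abort <- function(msg, class, call = NULL) {
  stop(errorCondition(msg, class = c(paste0("marref_", class), "marref_error")))
}

#' CT slice container
#'
#' A single axial CT slice in Hounsfield units together with its pixel
#' spacing. All pipeline stages consume and produce this container. Pixel
#' centres sit at integer (row, col) coordinates (1-based, R convention);
#' physical distances are computed as `(index - 1) * spacing_mm`.
#'
#' @param pixels Numeric matrix of HU values (rows x cols), all finite.
#' @param spacing_mm Numeric length-2 vector, pixel size in mm as
#'   `(row, col)`; both components must be positive.
#' @param origin_tag Free-text provenance (file path or simulation seed).
#'
#' @return An object of class `ct_image`: a list with elements `pixels`,
#'   `spacing_mm`, `origin_tag`.
#' @examples
#' img <- ct_image(matrix(0, 8, 8), spacing_mm = c(0.39, 0.39))
#' dim(img$pixels)
#' @export
ct_image <- function(pixels, spacing_mm, origin_tag = "in-memory") {
  if (!is.matrix(pixels) || !is.numeric(pixels)) {
    mar_abort("`pixels` must be a numeric matrix", "bad_input")
  }
  if (!all(is.finite(pixels))) {
    mar_abort("CT pixel values must all be finite", "bad_input")
  }
  spacing_mm <- as.numeric(spacing_mm)
  if (length(spacing_mm) == 1) spacing_mm <- rep(spacing_mm, 2)
  if (length(spacing_mm) != 2 || !all(is.finite(spacing_mm)) || any(spacing_mm <= 0)) {
    mar_abort("`spacing_mm` must be two positive finite values", "missing_spacing")
  }
  structure(
    list(pixels = pixels, spacing_mm = spacing_mm, origin_tag = as.character(origin_tag)[1]),
    class = "ct_image"
  )
}

#' @export
print.ct_image <- function(x, ...) {
  cat(sprintf(
    "<ct_image> %d x %d px, spacing %.4g x %.4g mm, HU range [%.0f, %.0f]\n  origin: %s\n",
    nrow(x$pixels), ncol(x$pixels), x$spacing_mm[1], x$spacing_mm[2],
    min(x$pixels), max(x$pixels), x$origin_tag
  ))
  invisible(x)
}

#' @export
dim.ct_image <- function(x) dim(x$pixels)

# Shared shape/spacing compatibility check.
check_same_grid <- function(a, b, what = "images") {
  if (!identical(dim(a$pixels %||% a$pixels), dim(b$pixels %||% b$pixels)) ||
      max(abs(a$spacing_mm - b$spacing_mm)) > 1e-6 * max(a$spacing_mm)) {
    mar_abort(paste(what, "must share grid shape and spacing"), "shape_mismatch")
  }
  invisible(TRUE)
}

#' Binary region mask
#'
#' A binary pixel set on the CT grid, tagged with the anatomical structure
#' it delineates and the zone (whole, or the near/far split around the
#' metal centroid).
#'
#' @param pixels Logical matrix.
#' @param structure One of `"metal"`, `"bone"`, `"tissue"` (or `"air"`,
#'   `"body"` for simulator ground truth and intermediates).
#' @param zone One of `"whole"`, `"near"`, `"far"`.
#' @param spacing_mm Pixel spacing in mm `(row, col)`.
#' @return An object of class `region_mask`.
#' @examples
#' m <- region_mask(matrix(c(TRUE, FALSE, FALSE, TRUE), 2), "bone", spacing_mm = c(1, 1))
#' sum(m$pixels)
#' @export
region_mask <- function(pixels, structure, zone = "whole", spacing_mm = c(1, 1)) {
  if (!is.matrix(pixels) || !is.logical(pixels)) {
    mar_abort("mask `pixels` must be a logical matrix", "bad_input")
  }
  structure_ <- match.arg(structure, c("metal", "bone", "tissue", "air", "body"))
  zone <- match.arg(zone, c("whole", "near", "far"))
  structure(
    list(pixels = pixels, structure = structure_, zone = zone,
         spacing_mm = as.numeric(spacing_mm)),
    class = "region_mask"
  )
}

#' @export
print.region_mask <- function(x, ...) {
  cat(sprintf("<region_mask> %s/%s: %d px on %d x %d grid\n",
              x$structure, x$zone, sum(x$pixels), nrow(x$pixels), ncol(x$pixels)))
  invisible(x)
}

# Pixel-count centroid of a mask in (row, col) coordinates.
mask_centroid <- function(mask) {
  px <- if (inherits(mask, "region_mask")) mask$pixels else mask
  idx <- which(px, arr.ind = TRUE)
  if (nrow(idx) == 0) mar_abort("cannot take centroid of empty mask", "empty_region")
  c(row = mean(idx[, 1]), col = mean(idx[, 2]))
}
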