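#' HU histogram of a masked region
#'
#' Uniform-width binning of the HU values under a mask, spanning the
#' region's min..max. The total count always equals the mask pixel count.
#'
#' @param image A [ct_image].
#' @param mask A [region_mask] on the same grid.
#' @param bin_width_hu Bin width in HU (> 0), default 1.
#' @param role Label of the image role (`"nonmar"`, `"mar"`, `"reference"`)
#'   recorded on the histogram.
#' @return An object of class `region_histogram`: list with `bin_edges`,
#'   `counts`, `bin_width_hu`, `source`.
#' @export
region_histogram <- function(image, mask, bin_width_hu = 1, role = "image") {
  if (bin_width_hu <= 0) mar_abort("bin_width_hu must be > 0", "bad_input")
  px <- if (inherits(image, "ct_image")) image$pixels else image
  sel <- if (inherits(mask, "region_mask")) mask$pixels else mask
  if (!identical(dim(px), dim(sel))) mar_abort("mask shape does not match image", "shape_mismatch")
  vals <- px[sel]
  if (length(vals) == 0) mar_abort("region is empty", "empty_region")
  lo <- min(vals)
  nbins <- max(1L, ceiling((max(vals) - lo) / bin_width_hu))
  if (lo + nbins * bin_width_hu <= max(vals)) nbins <- nbins + 1L
  bin <- pmin(floor((vals - lo) / bin_width_hu) + 1L, nbins)
  counts <- tabulate(bin, nbins = nbins)
  structure(
    list(bin_edges = lo + (0:nbins) * bin_width_hu, counts = counts,
         bin_width_hu = bin_width_hu,
         source = list(structure = if (inherits(mask, "region_mask")) mask$structure else NA,
                       zone = if (inherits(mask, "region_mask")) mask$zone else NA,
                       role = role)),
    class = "region_histogram"
  )
}

hist_centers <- function(h) (h$bin_edges[-1] + h$bin_edges[-length(h$bin_edges)]) / 2

#' @export
print.region_histogram <- function(x, ...) {
  cat(sprintf("<region_histogram> %s/%s (%s): %d px in %d bins of %g HU\n",
              x$source$structure, x$source$zone, x$source$role,
              sum(x$counts), length(x$counts), x$bin_width_hu))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @exportS3Method generics::tidy
tidy.region_histogram <- function(x, ...) {
  tibble::tibble(bin_center = hist_centers(x), count = x$counts)
}

new_gaussian_model <- function(centroid, sigma, amplitude, rss, method, converged, n_px) {
  structure(
    list(centroid_hu = centroid, sigma_hu = sigma, amplitude = amplitude,
         fit_rss = rss, method = method, converged = converged, n_px = n_px),
    class = "gaussian_model"
  )
}

#' @export
print.gaussian_model <- function(x, ...) {
  cat(sprintf("<gaussian_model> mu %.2f HU, sigma %.2f HU, amplitude %.1f (%s%s)\n",
              x$centroid_hu, x$sigma_hu, x$amplitude, x$method,
              if (x$converged) "" else ", not converged"))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.gaussian_model <- function(x, ...) {
  tibble::tibble(centroid_hu = x$centroid_hu, sigma_hu = x$sigma_hu,
                 amplitude = x$amplitude, fit_rss = x$fit_rss,
                 method = x$method, converged = x$converged, n_px = x$n_px)
}

#' Fit a Gaussian to a region histogram
#'
#' Least-squares fit of `A exp(-(x - mu)^2 / (2 sigma^2))` to the bin
#' centres and counts, initialised from the sample moments. The amplitude
#' is free (region counts are unnormalised); `mu` and `sigma` are unchanged
#' by that scaling choice. If the optimiser fails, the moment estimates are
#' returned instead, flagged via `method = "moments"` and a warning.
#'
#' @param hist A [region_histogram] with at least 5 informative bins
#'   spanning more than one bin width.
#' @return A `gaussian_model`: `centroid_hu` (mu), `sigma_hu`, `amplitude`,
#'   `fit_rss`, `method`, `converged`, `n_px`.
#' @export
fit_gaussian <- function(hist) {
  if (!inherits(hist, "region_histogram")) {
    mar_abort("`hist` must be a region_histogram", "bad_input")
  }
  x <- hist_centers(hist)
  y <- as.numeric(hist$counts)
  nz <- y > 0
  if (sum(nz) < 5 || diff(range(x[nz])) <= hist$bin_width_hu) {
    mar_abort("too few informative bins for a Gaussian fit", "degenerate_distribution")
  }
  n_px <- sum(y)
  wm <- sum(x * y) / n_px
  wsd <- sqrt(sum(y * (x - wm)^2) / n_px)
  if (wsd <= 0) mar_abort("zero-variance region", "degenerate_distribution")
  fit <- tryCatch(
    minpack.lm::nlsLM(
      y ~ A * exp(-(x - mu)^2 / (2 * sigma^2)),
      start = list(A = max(y), mu = wm, sigma = wsd),
      control = minpack.lm::nls.lm.control(maxiter = 200)
    ),
    error = function(e) NULL, warning = function(w) NULL
  )
  if (is.null(fit)) {
    warning("Gaussian fit failed; falling back to moment estimates",
            call. = FALSE)
    rss <- sum((y - max(y) * exp(-(x - wm)^2 / (2 * wsd^2)))^2)
    return(new_gaussian_model(wm, wsd, max(y), rss, "moments", FALSE, n_px))
  }
  cf <- stats::coef(fit)
  new_gaussian_model(unname(cf["mu"]), abs(unname(cf["sigma"])), unname(cf["A"]),
                     sum(stats::residuals(fit)^2), "least_squares", TRUE, n_px)
}

#' Full width at half maximum of a fitted Gaussian
#'
#' Two conventions are supported. The default (`"paper"`) is
#' `sqrt(2 ln 2) * sigma`; the `"conventional"` form is the textbook
#' `2 sqrt(2 ln 2) * sigma`, exactly twice as large. All four downstream
#' ratio metrics are quotients of FWHMs from the same convention and are
#' therefore identical under either choice.
#'
#' @param model A `gaussian_model` (or any object with `sigma_hu > 0`).
#' @param convention `"paper"` or `"conventional"`.
#' @return Width in HU.
#' @export
fwhm <- function(model, convention = c("paper", "conventional")) {
  convention <- match.arg(convention)
  sigma <- if (is.list(model)) model$sigma_hu else model
  if (!is.finite(sigma) || sigma <= 0) {
    mar_abort("sigma must be positive for a FWHM", "bad_input")
  }
  k <- sqrt(2 * log(2))
  if (convention == "conventional") k <- 2 * k
  k * sigma
}

#' Centroid of a fitted Gaussian
#'
#' The fitted mean `mu`, interpreted as the average HU of the structure.
#'
#' @param model A `gaussian_model`.
#' @return Centroid in HU.
#' @export
centroid <- function(model) {
  if (!is.list(model) || is.null(model$centroid_hu)) {
    mar_abort("`model` must be a gaussian_model", "bad_input")
  }
  model$centroid_hu
}
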