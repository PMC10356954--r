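#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Display a CT slice through a window/level ramp
#'
#' @param object A [ct_image].
#' @param window,level Display window width and centre in HU (default
#'   400/40, soft tissue).
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.ct_image <- function(object, window = 400, level = 40, ...) {
  px <- object$pixels
  df <- tibble::tibble(
    row = rep(seq_len(nrow(px)), ncol(px)),
    col = rep(seq_len(ncol(px)), each = nrow(px)),
    value = pmin(pmax((as.vector(px) - (level - window / 2)) / window, 0), 1)
  )
  ggplot2::ggplot(df, ggplot2::aes(.data$col, .data$row, fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient(low = "black", high = "white", limits = c(0, 1)) +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = NULL, y = NULL, fill = "W/L") +
    ggplot2::theme_void()
}

#' Histogram with its fitted Gaussian
#'
#' @param object A [region_histogram].
#' @param model Optional `gaussian_model` from [fit_gaussian()] to overlay.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.region_histogram <- function(object, model = NULL, ...) {
  df <- tidy(object)
  p <- ggplot2::ggplot(df, ggplot2::aes(.data$bin_center, .data$count)) +
    ggplot2::geom_col(width = object$bin_width_hu, fill = "grey65") +
    ggplot2::labs(x = "HU", y = "Frequency",
                  title = sprintf("%s / %s (%s)", object$source$structure,
                                  object$source$zone, object$source$role))
  if (!is.null(model)) {
    xx <- seq(min(df$bin_center), max(df$bin_center), length.out = 400)
    fitdf <- tibble::tibble(
      x = xx,
      y = model$amplitude * exp(-(xx - model$centroid_hu)^2 / (2 * model$sigma_hu^2))
    )
    p <- p + ggplot2::geom_line(data = fitdf, ggplot2::aes(.data$x, .data$y),
                                colour = "#d62728", linewidth = 0.8)
  }
  p
}

#' Ratio metrics of an evaluation report
#'
#' Bars of the four full-reference ratios per structure and zone, with the
#' reference level 1 marked: bars above 1 are regions wider (FWHM) or
#' shifted (centroid) relative to the metal-free reference.
#'
#' @param object A `mar_report` from [run_evaluation()].
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.mar_report <- function(object, ...) {
  long <- tidyr::pivot_longer(
    dplyr::select(object$metrics, "structure", "zone",
                  "fwhm_nm", "fwhm_m", "cent_nm", "cent_m"),
    cols = c("fwhm_nm", "fwhm_m", "cent_nm", "cent_m"),
    names_to = "metric", values_to = "ratio"
  )
  long$zone <- factor(long$zone, levels = c("whole", "near", "far"))
  long$metric <- factor(long$metric, levels = c("fwhm_nm", "fwhm_m", "cent_nm", "cent_m"),
                        labels = c("FWHM_NM", "FWHM_M", "CENT_NM", "CENT_M"))
  ggplot2::ggplot(long, ggplot2::aes(.data$zone, .data$ratio, fill = .data$metric)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::geom_hline(yintercept = 1, linetype = 2) +
    ggplot2::facet_wrap(~structure) +
    ggplot2::scale_fill_brewer(palette = "Set2") +
    ggplot2::labs(x = NULL, y = "Ratio to reference", fill = NULL)
}

#' @importFrom rlang .data
NULL
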