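#' Tidy methods for rasters and curves
#'
#' `tidy()` converts sinograms and images to long tibbles for plotting or
#' further dplyr work.
#'
#' @param x A `dex_sinogram` or `dex_image`.
#' @param ... Unused.
#' @return A long tibble.
#' @export
tidy.dex_sinogram <- function(x, ...) {
  tidyr::expand_grid(view = seq_len(nrow(x$data)),
                     channel = seq_len(ncol(x$data))) |>
    dplyr::mutate(value = as.vector(t(x$data)))
}

#' @rdname tidy.dex_sinogram
#' @export
tidy.dex_image <- function(x, ...) {
  n <- nrow(x$values)
  px <- x$fov / n
  vals <- as.vector(t(x$values))
  tidyr::expand_grid(row = seq_len(n), col = seq_len(n)) |>
    dplyr::mutate(x = (.data$col - 0.5 - n / 2) * px,
                  y = (.data$row - 0.5 - n / 2) * px,
                  value = vals)
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot methods
#'
#' `autoplot()` methods give quick ggplot2 views of spectra, allocation
#' curves, energy curves, images and sinograms.
#'
#' @param object The object to plot.
#' @param ... Unused.
#' @name autoplot-dexct
NULL

#' @rdname autoplot-dexct
#' @export
autoplot.dex_spectrum <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(.data$energy_kev,
                                       .data$photons_per_bin)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "Energy (keV)", y = "Photons per bin",
                  title = spectrum_label(object))
}

#' @rdname autoplot-dexct
#' @export
autoplot.dex_allocation <- function(object, ...) {
  df <- tidyr::pivot_longer(tibble::as_tibble(object),
                            c("snr_tissue", "snr_bone"),
                            names_to = "material", values_to = "snr",
                            names_prefix = "snr_")
  ggplot2::ggplot(df, ggplot2::aes(.data$r, .data$snr,
                                   colour = .data$material)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "Dose fraction to high-energy spectrum r",
                  y = "Basis material SNR",
                  title = attr(object, "pair_label"))
}

#' @rdname autoplot-dexct
#' @export
autoplot.dex_energy_curve <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(.data$energy, .data$cnr)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "VMI energy (keV)", y = "CNR")
}

#' @rdname autoplot-dexct
#' @param window Display window width (HU or image units).
#' @param level Display window level.
#' @export
autoplot.dex_image <- function(object, window = NULL, level = NULL, ...) {
  df <- tidy(object)
  if (!is.null(window)) {
    if (is.null(level)) level <- 0
    lo <- level - window / 2
    hi <- level + window / 2
    df$value <- pmin(pmax(df$value, lo), hi)
  }
  ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y, fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::coord_equal() +
    ggplot2::scale_fill_gradient(low = "black", high = "white") +
    ggplot2::labs(x = "x (cm)", y = "y (cm)", fill = object$kind)
}

#' @rdname autoplot-dexct
#' @export
autoplot.dex_sinogram <- function(object, ...) {
  ggplot2::ggplot(tidy(object), ggplot2::aes(.data$channel, .data$view,
                                             fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::labs(x = "Channel", y = "View", fill = object$content_kind)
}

#' @importFrom rlang .data
NULL
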