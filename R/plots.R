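# ggplot2 graphics for spectra tables and fitted objects.

class_labels <- c(`0` = "normal", `1` = "bloody", `2` = "yolk-destroyed")

#' Plot spectra coloured by egg class
#'
#' @param df Spectra tibble.
#' @param by_class Draw per-class mean spectra instead of individual scans
#'   (default `TRUE`; individual scans of a 750-row set overplot heavily).
#' @return A ggplot.
#' @export
plot_spectra <- function(df, by_class = TRUE) {
  long <- tidyr::pivot_longer(df, cols = dplyr::all_of(wl_cols(df)),
                              names_to = "wavelength", values_to = "value")
  long$wavelength <- as.numeric(long$wavelength)
  has_class <- "class" %in% names(long) && !all(is.na(long$class))
  if (by_class && has_class) {
    long <- dplyr::summarise(dplyr::group_by(long, .data$class, .data$wavelength),
                             value = mean(.data$value), .groups = "drop")
  }
  p <- ggplot2::ggplot(long, ggplot2::aes(.data$wavelength, .data$value))
  if (has_class) {
    p <- p + ggplot2::geom_line(ggplot2::aes(
      colour = factor(.data$class, names(class_labels), class_labels),
      group = if (by_class) .data$class else interaction(.data$egg_id, .data$rotation)
    ))
  } else {
    p <- p + ggplot2::geom_line()
  }
  p + ggplot2::labs(x = "wavelength (nm)", y = "intensity", colour = "class") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.plsda <- function(object, weighted = TRUE, ...) {
  wb <- weighted_beta(object)
  y <- if (weighted) wb$weighted_beta else wb$beta
  ggplot2::ggplot(tibble(wavelength = wb$wavelength, coef = y),
                  ggplot2::aes(.data$wavelength, .data$coef)) +
    ggplot2::geom_line() +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey50") +
    ggplot2::labs(x = "wavelength (nm)",
                  y = if (weighted) "weighted beta coefficient" else "beta coefficient") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.selection_result <- function(object, ...) {
  ggplot2::ggplot(tidy(object), ggplot2::aes(.data$wavelength, 1)) +
    ggplot2::geom_segment(ggplot2::aes(xend = .data$wavelength, y = 0, yend = 1)) +
    ggplot2::geom_point(ggplot2::aes(y = 1)) +
    ggplot2::labs(x = "wavelength (nm)", y = NULL, title = object$method) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.y = ggplot2::element_blank())
}

#' @export
autoplot.cascade_result <- function(object, ...) {
  rep <- object$report
  ggplot2::ggplot(rep, ggplot2::aes(.data$n_bands, .data$total_acc)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::scale_x_reverse(breaks = rep$n_bands) +
    ggplot2::labs(x = "number of bands", y = "validation total accuracy (%)") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
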