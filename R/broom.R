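# broom-style accessors for fitted objects.

#' Tidy a PLS-DA model
#'
#' @param x A fitted [plsda_fit()] model.
#' @param ... Unused.
#' @return Tibble with one row per wavelength: `wavelength`, `beta`, `sd`
#'   (training column sd) and `weighted_beta`.
#' @export
tidy.plsda <- function(x, ...) {
  weighted_beta(x)
}

#' Summarise a PLS-DA model in one row
#'
#' @param x A fitted [plsda_fit()] model.
#' @param ... Unused.
#' @return One-row tibble: latent variables, training dimensions, residual
#'   norms of the X and y decompositions.
#' @export
glance.plsda <- function(x, ...) {
  tibble(
    n_components = x$A, n = x$n, p = x$p,
    x_residual_norm = norm(x$E, "F"),
    y_residual_norm = sqrt(sum(x$F^2)),
    y_mean = x$y_mean
  )
}

#' Augment spectra with PLS-DA predictions
#'
#' @param x A fitted [plsda_fit()] model.
#' @param data Spectra tibble on the model's axis.
#' @param ... Unused.
#' @return The metadata of `data` with `.score` and `.pred` columns.
#' @export
augment.plsda <- function(x, data, ...) {
  predict(x, data)
}

#' @export
tidy.classification_report <- function(x, ...) {
  x$per_class
}

#' @export
glance.classification_report <- function(x, ...) {
  tibble(n = x$n, total_accuracy = x$total_accuracy)
}
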