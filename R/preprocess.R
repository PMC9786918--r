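# Spectral pretreatments: scaling normalisations, standard normal variate,
# multiplicative scatter correction and Savitzky-Golay derivatives. All are
# pure per-spectrum transforms except MSC, whose reference spectrum is learned
# from training rows only and replayed on validation rows.

#' Per-spectrum normalisations
#'
#' `mean_norm()` divides by the spectrum mean, `max_norm()` by its maximum,
#' and `range_norm()` maps it affinely onto `[0, 1]`.
#'
#' @param x Numeric intensity vector.
#' @param label Optional name used in error messages.
#' @return Transformed numeric vector of the same length.
#' @examples
#' mean_norm(c(2, 4, 6)) # 0.5 1.0 1.5
#' @export
mean_norm <- function(x, label = "spectrum") {
  m <- mean(x)
  if (!is.finite(m) || m == 0) abort(paste0("mean_norm: ", label, " has mean 0"))
  x / m
}

#' @rdname mean_norm
#' @export
max_norm <- function(x, label = "spectrum") {
  m <- max(x)
  if (!is.finite(m) || m == 0) abort(paste0("max_norm: ", label, " has max 0"))
  x / m
}

#' @rdname mean_norm
#' @export
range_norm <- function(x, label = "spectrum") {
  lo <- min(x); hi <- max(x)
  if (!is.finite(hi - lo) || hi <= lo) abort(paste0("range_norm: ", label, " is constant"))
  (x - lo) / (hi - lo)
}

#' Standard normal variate
#'
#' Centers and scales one spectrum to mean 0 and sample (n-1) standard
#' deviation 1, removing per-scan offset and scale effects.
#'
#' @inheritParams mean_norm
#' @return Numeric vector with mean 0 and sample sd 1.
#' @export
snv <- function(x, label = "spectrum") {
  s <- sd(x)
  if (!is.finite(s) || s == 0) abort(paste0("snv: ", label, " is constant"))
  (x - mean(x)) / s
}

#' Multiplicative scatter correction
#'
#' `msc_fit()` learns the reference spectrum (the column mean of the training
#' matrix); `msc_apply()` regresses a spectrum on the reference
#' (`x ~ a + b * reference`, ordinary least squares) and returns
#' `(x - a) / b`.
#'
#' @param X Training matrix (rows = scans) for `msc_fit()`.
#' @param x Spectrum to correct.
#' @param reference Reference spectrum from `msc_fit()`.
#' @param label Optional name used in error messages.
#' @return `msc_fit()`: the reference spectrum. `msc_apply()`: the corrected
#'   spectrum.
#' @export
msc_fit <- function(X) {
  if (is.null(dim(X)) || nrow(X) < 1L) abort("msc_fit needs a matrix with >= 1 row")
  colMeans(X)
}

#' @rdname msc_fit
#' @export
msc_apply <- function(x, reference, label = "spectrum") {
  if (length(x) != length(reference)) abort("msc_apply: length mismatch with reference")
  rc <- reference - mean(reference)
  b <- sum(rc * x) / sum(rc * rc)
  a <- mean(x) - b * mean(reference)
  if (!is.finite(b) || abs(b) <= 1e-12) {
    abort(paste0("msc_apply: ", label, " is uncorrelated with the reference"))
  }
  (x - a) / b
}

# Savitzky-Golay derivative coefficients for offsets d (nm) around the
# evaluation point: least-squares polynomial fit, analytic derivative at 0.
sg_coeffs <- function(d, polyorder, deriv) {
  V <- outer(d, 0:polyorder, `^`)
  # row `deriv` of the pseudo-inverse, times deriv! — the derivative of the
  # fitted polynomial at offset 0.
  Pinv <- solve(crossprod(V), t(V))
  factorial(deriv) * Pinv[deriv + 1L, ]
}

#' Savitzky-Golay derivative
#'
#' Local polynomial least-squares derivative of a spectrum, scaled by the
#' grid spacing so the result is a derivative per nm and independent of the
#' axis resolution. Edge points are handled by refitting the polynomial on
#' the truncated window (no padding).
#'
#' @param x Numeric intensity vector.
#' @param axis Wavelengths (nm), strictly increasing, uniform spacing.
#' @param deriv Derivative order, 1 or 2.
#' @param window Odd window width >= 5 (number of grid points).
#' @param polyorder Polynomial order, `deriv <= polyorder < window`.
#' @return Numeric vector of the derivative, same length as `x`.
#' @examples
#' axis <- seq(500, 600, by = 1)
#' savitzky_golay(2 * axis, axis, deriv = 1)[5] # 2
#' @export
savitzky_golay <- function(x, axis, deriv = 1, window = 11, polyorder = 2) {
  p <- length(x)
  if (length(axis) != p) abort("savitzky_golay: x and axis lengths differ")
  check_axis(axis)
  if (window %% 2 != 1 || window < 5) abort("window must be an odd integer >= 5")
  if (window > p) abort("window exceeds spectrum length")
  if (!deriv %in% c(1, 2)) abort("deriv must be 1 or 2")
  if (polyorder < deriv || polyorder >= window) abort("need deriv <= polyorder < window")
  h <- diff(axis)
  # spectra tibbles carry wavelengths rounded to 0.01 nm in the column names,
  # so an evenly sampled grid shows ~1% spacing jitter; treat it as uniform
  if (max(h) - min(h) > 0.05 * mean(h)) abort("savitzky_golay requires a uniform axis")
  h <- mean(h)
  hw <- (window - 1L) %/% 2L
  out <- numeric(p)
  # interior: one fixed coefficient vector, applied as a shifted weighted sum;
  # subtracting the centre value makes the operator annihilate constants
  # exactly (the coefficients sum to zero only up to rounding)
  co <- sg_coeffs(h * (-hw:hw), polyorder, deriv)
  interior <- (hw + 1L):(p - hw)
  acc <- numeric(length(interior))
  for (k in seq_along(co)) {
    acc <- acc + co[k] * (x[interior + (k - 1L - hw)] - x[interior])
  }
  out[interior] <- acc
  # edges: truncated window refit
  for (i in c(seq_len(hw), (p - hw + 1L):p)) {
    idx <- max(1L, i - hw):min(p, i + hw)
    out[i] <- sum(sg_coeffs(axis[idx] - axis[i], polyorder, deriv) * (x[idx] - x[i]))
  }
  out
}

#' Declare a preprocessing method
#'
#' Creates an (unfitted) preprocessing specification that [preprocess_fit()]
#' completes on training data and [preprocess_apply()] replays on any data.
#' Only MSC carries fitted state (the training-mean reference spectrum); all
#' other methods are pure per-spectrum transforms.
#'
#' @param method One of `"none"`, `"mean_norm"`, `"max_norm"`, `"range_norm"`,
#'   `"snv"`, `"msc"`, `"sg1"`, `"sg2"`.
#' @param sg_window,sg_polyorder Savitzky-Golay window (odd, >= 5) and
#'   polynomial order, used by `"sg1"`/`"sg2"`.
#' @return A list of class `preprocess_spec`.
#' @export
preprocess_spec <- function(method = c("none", "mean_norm", "max_norm", "range_norm",
                                       "snv", "msc", "sg1", "sg2"),
                            sg_window = 11, sg_polyorder = 2) {
  method <- match.arg(method)
  if (sg_window %% 2 != 1 || sg_window < 5) abort("sg_window must be an odd integer >= 5")
  if (sg_polyorder < 2 || sg_polyorder >= sg_window) abort("need 2 <= sg_polyorder < sg_window")
  structure(
    list(method = method, sg_window = sg_window, sg_polyorder = sg_polyorder,
         fitted_state = NULL),
    class = "preprocess_spec"
  )
}

#' Fit a preprocessing spec on training data
#'
#' @param spec A [preprocess_spec()].
#' @param train Training spectra tibble.
#' @return The spec with `fitted_state` filled (MSC reference) where the
#'   method needs training statistics.
#' @export
preprocess_fit <- function(spec, train) {
  stopifnot(inherits(spec, "preprocess_spec"))
  if (spec$method == "msc") {
    spec$fitted_state <- list(reference = msc_fit(spectra_matrix(train)),
                              axis = spectra_axis(train))
  }
  spec
}

#' Apply a (fitted) preprocessing spec to spectra
#'
#' @param spec A [preprocess_spec()], fitted with [preprocess_fit()] if the
#'   method requires training statistics.
#' @param df Spectra tibble.
#' @return Transformed spectra tibble of the same shape.
#' @export
preprocess_apply <- function(spec, df) {
  stopifnot(inherits(spec, "preprocess_spec"))
  mat <- spectra_matrix(df)
  axis <- spectra_axis(df)
  labels <- if ("egg_id" %in% names(df)) df$egg_id else paste0("row ", seq_len(nrow(mat)))
  out <- switch(
    spec$method,
    none = mat,
    mean_norm = t(vapply(seq_len(nrow(mat)), function(i) mean_norm(mat[i, ], labels[i]), numeric(ncol(mat)))),
    max_norm = t(vapply(seq_len(nrow(mat)), function(i) max_norm(mat[i, ], labels[i]), numeric(ncol(mat)))),
    range_norm = t(vapply(seq_len(nrow(mat)), function(i) range_norm(mat[i, ], labels[i]), numeric(ncol(mat)))),
    snv = t(vapply(seq_len(nrow(mat)), function(i) snv(mat[i, ], labels[i]), numeric(ncol(mat)))),
    msc = {
      if (is.null(spec$fitted_state)) abort("msc spec must be fitted with preprocess_fit() first")
      check_same_axis(axis, spec$fitted_state$axis, "data and MSC reference")
      ref <- spec$fitted_state$reference
      t(vapply(seq_len(nrow(mat)), function(i) msc_apply(mat[i, ], ref, labels[i]), numeric(ncol(mat))))
    },
    sg1 = t(apply(mat, 1, savitzky_golay, axis = axis, deriv = 1,
                  window = spec$sg_window, polyorder = spec$sg_polyorder)),
    sg2 = t(apply(mat, 1, savitzky_golay, axis = axis, deriv = 2,
                  window = spec$sg_window, polyorder = spec$sg_polyorder))
  )
  build_spectra(spectra_meta(df), out, axis)
}
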