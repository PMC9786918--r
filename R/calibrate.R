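# Intensity calibration: raw detector counts B to relative transmittance
# T = (B - D) / (W - D) against averaged white (W) and dark (D) references,
# and restriction of the working wavelength range.

#' Average repeated scans point-wise
#'
#' @param scans Spectra tibble whose rows are repeated scans on a shared axis.
#' @return One-row spectra tibble of point-wise means; metadata is taken from
#'   the first scan and the number of scans averaged is recorded in the
#'   `n_averaged` attribute.
#' @examples
#' cfg <- sim_config(axis = seq(500, 600, by = 10))
#' s <- dplyr::bind_rows(simulate_scan(cfg, 0), simulate_scan(cfg, 0, seed = 2))
#' average_scans(s)
#' @export
average_scans <- function(scans) {
  if (nrow(scans) == 0L) abort("average_scans() needs at least one scan")
  mat <- spectra_matrix(scans)
  out <- build_spectra(spectra_meta(scans)[1, , drop = FALSE],
                       matrix(colMeans(mat), nrow = 1),
                       spectra_axis(scans))
  attr(out, "n_averaged") <- nrow(scans)
  out
}

#' Calibrate raw scans to relative transmittance
#'
#' Applies `T = (B - D) / (W - D)` point-wise, where `W` and `D` are the
#' white and dark reference spectra. Axis points where `W - D` is at or below
#' a guard (`1e-9 * max(W - D)`) carry no usable light (e.g. outside the lamp
#' support) and are flagged undefined: their transmittance is `NA` and they
#' must be dropped (see [restrict_range()]) before any modelling.
#'
#' @param df Spectra tibble of raw scans.
#' @param refs References tibble (`ref` column with rows `white` and `dark`)
#'   on the same axis.
#' @return Spectra tibble of the same shape with `kind = "transmittance"`;
#'   undefined points are `NA`.
#' @export
calibrate <- function(df, refs) {
  axis <- spectra_axis(df)
  check_same_axis(axis, spectra_axis(refs), "scans and references")
  W <- as.numeric(spectra_matrix(refs)[match("white", refs$ref), ])
  D <- as.numeric(spectra_matrix(refs)[match("dark", refs$ref), ])
  denom <- W - D
  guard <- 1e-9 * max(denom)
  defined <- denom > guard
  if (!any(defined)) abort("calibration undefined everywhere: W - D <= guard at every point")
  B <- spectra_matrix(df)
  Tm <- sweep(sweep(B, 2, D, "-"), 2, denom, "/")
  Tm[, !defined] <- NA_real_
  meta <- spectra_meta(df)
  if ("kind" %in% names(meta)) meta$kind <- "transmittance" else meta$kind <- "transmittance"
  build_spectra(meta, Tm, axis)
}

#' Restrict a spectra tibble to a wavelength window
#'
#' Keeps the grid points with `lo_nm <= wavelength <= hi_nm`, dropping any
#' column flagged undefined by [calibrate()] (i.e. containing `NA`). Points
#' are never reordered or interpolated.
#'
#' @param df Spectra tibble.
#' @param lo_nm,hi_nm Window bounds in nm, `lo_nm < hi_nm`.
#' @return Spectra tibble with the retained wavelength columns.
#' @export
restrict_range <- function(df, lo_nm, hi_nm) {
  if (!(lo_nm < hi_nm)) abort("lo_nm must be < hi_nm")
  axis <- spectra_axis(df)
  mat <- spectra_matrix(df)
  keep <- axis >= lo_nm & axis <= hi_nm & colSums(is.na(mat)) == 0L
  if (!any(keep)) abort("restrict_range(): no defined wavelengths left in the window")
  build_spectra(spectra_meta(df), mat[, keep, drop = FALSE], axis[keep])
}
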