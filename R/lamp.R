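# Lamp emission envelopes, eggshell transmission and absorber band shapes used
# by the synthetic scan generator.

# Smooth compact-support bump: sin^2 arch on (lo, hi), exactly 0 outside.
# A small pedestal keeps the envelope bounded away from 0 across the closed
# support, emulating the broadband leakage of coated halogen lamps.
support_bump <- function(axis, lo, hi, pedestal = 0.05) {
  inside <- axis >= lo & axis <= hi
  arch <- ifelse(inside, sin(pi * pmin(pmax((axis - lo) / (hi - lo), 0), 1))^2, 0)
  arch + pedestal * inside
}

#' Emission envelope of a coated halogen lamp
#'
#' Returns the relative spectral emission of the two lamp coatings used for
#' egg candling. The silver coating emits only between 400 and 700 nm with a
#' pronounced maximum in the blood-sensitive 565--585 nm region; the gold
#' coating emits broadly between 500 and 1100 nm with its maximum in the red /
#' NIR. Outside the coating's support the envelope is exactly zero.
#'
#' @param name `"silver"` or `"gold"`.
#' @param axis Numeric vector of wavelengths (nm), strictly increasing.
#' @return A tibble with columns `wavelength` and `intensity` (relative units,
#'   nonnegative), one row per axis point, plus attributes `support` (length-2
#'   numeric) and `lamp` (the name).
#' @examples
#' lp <- lamp_profile("silver", seq(400, 700, by = 1))
#' @export
lamp_profile <- function(name, axis) {
  check_axis(axis)
  name <- match.arg(name, c("silver", "gold"))
  if (name == "silver") {
    support <- c(400, 700)
    # Gaussian emphasis around the hemoglobin band pins the peak near 577 nm.
    env <- support_bump(axis, 400, 700) *
      (0.35 + exp(-(axis - 577)^2 / (2 * 25^2)))
  } else {
    support <- c(500, 1100)
    env <- support_bump(axis, 500, 1100)
  }
  out <- tibble(wavelength = axis, intensity = env)
  attr(out, "support") <- support
  attr(out, "lamp") <- name
  out
}

# Logistic shell-transmission factor: calcium carbonate suppresses
# transmission below ~550 nm; the factor rises through 550 nm.
shell_transmission <- function(axis, center = 550, scale = 15) {
  1 / (1 + exp(-(axis - center) / scale))
}

# Gaussian absorber band evaluated on the axis (unit peak at the center).
absorber_band <- function(axis, center_nm, width_nm = 10) {
  stopifnot(width_nm > 0)
  exp(-(axis - center_nm)^2 / (2 * width_nm^2))
}

# The chromophores the generator models. Hemoglobin marks bloody eggs;
# protoporphyrin IX is the brown-shell pigment present in every egg; the
# yolk marker is a narrow feature in the 590--600 nm region distinguishing
# yolk-destroyed eggs.
absorber_centers <- function() {
  list(
    hemoglobin = c(415, 539, 577),
    ppix = c(539, 589, 643),
    yolk_marker = 596
  )
}

# Total absorbance profile for one scan: sum over chromophores of
# concentration x unit-peak Gaussian bands.
absorbance_profile <- function(axis, conc, band_sd = 10, yolk_sd = 4) {
  ctr <- absorber_centers()
  prof <- numeric(length(axis))
  for (c0 in ctr$hemoglobin) prof <- prof + conc[["hemoglobin"]] * absorber_band(axis, c0, band_sd)
  for (c0 in ctr$ppix) prof <- prof + conc[["ppix"]] * absorber_band(axis, c0, band_sd)
  prof + conc[["yolk_marker"]] * absorber_band(axis, ctr$yolk_marker, yolk_sd)
}
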