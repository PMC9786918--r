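# Synthetic candling-spectrum generator. Raw detector intensity for one scan:
#
#   B(lambda) = m * L(lambda) * S(lambda) * exp(-l * sum_i c_i G_i(lambda)) * a
#               + baseline(lambda) + stray(lambda) + eps(lambda),  clipped at 0
#
# with L the lamp envelope, S the logistic shell-transmission factor, G_i
# unit-peak Gaussian absorber bands (hemoglobin 415/539/577 nm, PPIX
# 539/589/643 nm, a yolk marker at 596 nm), l the geometry path-length scale,
# m a per-scan multiplicative scatter draw, a <= 1 a per-class global
# attenuation, stray a fraction of unattenuated lamp light bypassing the egg,
# and eps additive detector noise.

# Geometry conditions reduce to (path-length scale, stray-light fraction).
condition_params <- function(condition) {
  # condition 2 (sensor on the blunt end, light at 45 degrees) gives the
  # longest effective path through the egg contents and the least stray
  # light, hence the cleanest absorption signal; condition 1 (perpendicular
  # illumination) the shortest
  map <- list(
    `1` = c(path = 0.3, stray = 0.10),
    `2` = c(path = 1.2, stray = 0.02),
    `3` = c(path = 1.0, stray = 0.05)
  )
  key <- as.character(condition)
  if (!key %in% names(map)) abort("condition must be 1, 2 or 3")
  map[[key]]
}

# Per-class chromophore concentrations and global attenuation. Class coding:
# 0 = normal, 1 = bloody, 2 = yolk-destroyed.
# Hemoglobin is kept in the weak-absorption regime (bloody transmittance at
# the 577 nm center stays above the normal/yolk midpoint) so the band is
# informative at its center rather than on its flanks; the yolk class is
# globally dimmed with a narrow secondary marker in the 590--600 nm region.
default_class_params <- function() {
  list(
    `0` = list(conc = c(hemoglobin = 0.02, ppix = 0.15, yolk_marker = 0.0), atten = 1.00),
    `1` = list(conc = c(hemoglobin = 0.16, ppix = 0.15, yolk_marker = 0.0), atten = 0.95),
    `2` = list(conc = c(hemoglobin = 0.02, ppix = 0.15, yolk_marker = 0.5), atten = 0.50)
  )
}

#' Configuration for the synthetic spectra generator
#'
#' Bundles every knob of the simulator: wavelength axis, lamp coating,
#' measurement geometry, design size, per-class chromophore concentrations,
#' and noise levels. The defaults reproduce the study design the package
#' models: a 2068-point axis spanning 192--1110 nm and 50 eggs per class
#' measured at 5 rotations each (750 scans).
#'
#' @param axis Wavelength grid in nm, strictly increasing. Default
#'   `seq(192, 1110, length.out = 2068)`.
#' @param lamp `"silver"` or `"gold"`.
#' @param condition Measurement geometry, 1, 2 or 3. Internally mapped to a
#'   (path-length scale, stray-light fraction) pair; condition 2 has the
#'   longest path and least stray light.
#' @param n_eggs_per_class Eggs per class (default 50).
#' @param rotations_per_egg Scans per egg (default 5). Rotations share the
#'   egg's latent concentrations but redraw scatter, baseline and noise.
#' @param class_params Per-class list with elements `conc` (named numeric:
#'   `hemoglobin`, `ppix`, `yolk_marker`) and `atten` (global attenuation,
#'   <= 1). Names `"0"`, `"1"`, `"2"`.
#' @param noise_sd Additive detector noise sd (default 0.003).
#' @param scatter_sd Log-sd of the per-scan multiplicative scatter draw
#'   (default 0.15).
#' @param baseline_amp Maximum amplitude of the slow sinusoidal baseline
#'   drift (default 0.0005).
#' @param egg_sdlog Log-sd of the per-egg latent concentration draw around
#'   the class mean (default 0.12).
#' @param band_sd Gaussian sd (nm) of the hemoglobin/PPIX absorber bands
#'   (default 10).
#' @param teflon_factor Reflectance factor of the white reference disk
#'   (default 0.9).
#' @param dark_offset Small positive sensor offset of the dark reference
#'   (default 0.005).
#' @param path_scale,stray_frac Optional overrides of the geometry pair
#'   implied by `condition` (path-length scale and stray-light fraction);
#'   `NULL` (default) uses the condition map.
#' @param seed Integer seed; all randomness derives from it.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(axis = seq(192, 1110, length.out = 2068),
                       lamp = c("silver", "gold"),
                       condition = 2,
                       n_eggs_per_class = 50,
                       rotations_per_egg = 5,
                       class_params = default_class_params(),
                       noise_sd = 0.003,
                       scatter_sd = 0.15,
                       baseline_amp = 0.0005,
                       egg_sdlog = 0.12,
                       band_sd = 10,
                       teflon_factor = 0.9,
                       dark_offset = 0.005,
                       path_scale = NULL,
                       stray_frac = NULL,
                       seed = 1L) {
  check_axis(axis)
  lamp <- match.arg(lamp)
  condition_params(condition) # validates
  stopifnot(
    n_eggs_per_class >= 1, rotations_per_egg >= 1,
    noise_sd >= 0, scatter_sd >= 0, baseline_amp >= 0, egg_sdlog >= 0,
    band_sd > 0
  )
  for (k in c("0", "1", "2")) {
    cp <- class_params[[k]]
    if (is.null(cp) || cp$atten > 1 || any(cp$conc < 0)) {
      abort("class_params must give conc >= 0 and atten <= 1 for classes 0, 1, 2")
    }
  }
  structure(
    list(
      axis = axis, lamp = lamp, condition = condition,
      n_eggs_per_class = as.integer(n_eggs_per_class),
      rotations_per_egg = as.integer(rotations_per_egg),
      class_params = class_params,
      noise_sd = noise_sd, scatter_sd = scatter_sd,
      baseline_amp = baseline_amp, egg_sdlog = egg_sdlog,
      band_sd = band_sd, teflon_factor = teflon_factor,
      dark_offset = dark_offset,
      path_scale = path_scale, stray_frac = stray_frac,
      seed = as.integer(seed)
    ),
    class = "sim_config"
  )
}

# Deterministic part of one scan, given concentrations, scatter draw m and
# the per-scan stray-light factor u (u = 1 is the nominal stray fraction;
# stray light fluctuates with egg positioning, so scans redraw u).
scan_mean <- function(cfg, conc, atten, m = 1, u = 1) {
  cp <- condition_params(cfg$condition)
  if (!is.null(cfg$path_scale)) cp[["path"]] <- cfg$path_scale
  if (!is.null(cfg$stray_frac)) cp[["stray"]] <- cfg$stray_frac
  L <- lamp_profile(cfg$lamp, cfg$axis)$intensity
  S <- shell_transmission(cfg$axis)
  A <- absorbance_profile(cfg$axis, conc, band_sd = cfg$band_sd)
  m * L * S * exp(-cp[["path"]] * A) * atten + cp[["stray"]] * u * L
}

#' Simulate one raw transmittance scan
#'
#' Draws one detector-intensity spectrum for an egg of the given class under
#' the configured lamp, geometry and noise model. Bloody eggs carry a higher
#' hemoglobin concentration than normal eggs; yolk-destroyed eggs differ
#' from normal chiefly by a stronger global attenuation and a narrow local
#' feature in the 590--600 nm region.
#'
#' @param cfg A [sim_config()].
#' @param egg_class 0 (normal), 1 (bloody) or 2 (yolk-destroyed).
#' @param conc Optional named concentration vector overriding the class mean
#'   (used by [simulate_dataset()] to share per-egg latents across rotations).
#' @param seed Integer seed for this scan's noise draws; default derives from
#'   the config seed.
#' @return A one-row spectra tibble (`egg_id`, `class`, `lamp`, `condition`,
#'   `rotation`, `kind = "raw"`, then one column per wavelength).
#' @export
simulate_scan <- function(cfg, egg_class, conc = NULL, seed = derive_seed(cfg$seed, "scan")) {
  stopifnot(inherits(cfg, "sim_config"))
  if (!egg_class %in% 0:2) abort("egg_class must be 0, 1 or 2")
  cp <- cfg$class_params[[as.character(egg_class)]]
  if (is.null(conc)) conc <- cp$conc
  vals <- with_seed(seed, {
    m <- if (cfg$scatter_sd > 0) rlnorm(1, 0, cfg$scatter_sd) else 1
    u <- runif(1, 0.5, 1.5)
    mu <- scan_mean(cfg, conc, cp$atten, m = m, u = u)
    baseline <- if (cfg$baseline_amp > 0) {
      amp <- runif(1, 0, cfg$baseline_amp)
      phase <- runif(1, 0, 2 * pi)
      amp * sin(2 * pi * (cfg$axis - min(cfg$axis)) / diff(range(cfg$axis)) + phase)
    } else {
      0
    }
    eps <- if (cfg$noise_sd > 0) rnorm(length(cfg$axis), 0, cfg$noise_sd) else 0
    pmax(mu + baseline + eps, 0)
  })
  meta <- tibble(
    egg_id = NA_character_, class = as.integer(egg_class),
    lamp = cfg$lamp, condition = as.integer(cfg$condition),
    rotation = 1L, kind = "raw"
  )
  build_spectra(meta, matrix(vals, nrow = 1), cfg$axis)
}

#' Simulate white and dark calibration references
#'
#' The white reference is the lamp viewed through a Teflon disk (10 draws,
#' averaged); the dark reference is the sensor offset with the tube closed
#' (10 draws, averaged).
#'
#' @param cfg A [sim_config()].
#' @param n_scans Scans averaged per reference (default 10).
#' @return A two-row tibble with a `ref` column (`"white"`, `"dark"`) followed
#'   by one column per wavelength.
#' @export
simulate_references <- function(cfg, n_scans = 10) {
  stopifnot(inherits(cfg, "sim_config"), n_scans >= 1)
  L <- lamp_profile(cfg$lamp, cfg$axis)$intensity
  p <- length(cfg$axis)
  refs <- with_seed(derive_seed(cfg$seed, "references"), {
    w_draws <- replicate(n_scans, L * cfg$teflon_factor + rnorm(p, 0, cfg$noise_sd))
    d_draws <- replicate(n_scans, cfg$dark_offset + rnorm(p, 0, cfg$noise_sd))
    list(white = rowMeans(w_draws), dark = rowMeans(d_draws))
  })
  mat <- rbind(refs$white, refs$dark)
  out <- build_spectra(tibble(ref = c("white", "dark")), mat, cfg$axis)
  attr(out, "n_scans_averaged") <- as.integer(n_scans)
  out
}

#' Generate a labelled synthetic dataset with calibration references
#'
#' Draws `n_eggs_per_class` eggs for each of the three classes and scans each
#' egg `rotations_per_egg` times. Rotations of one egg share its latent
#' chromophore concentrations (drawn log-normally around the class means) but
#' redraw scatter, baseline and detector noise. With the defaults this yields
#' 750 raw scans (50 eggs x 3 classes x 5 rotations).
#'
#' @param cfg A [sim_config()].
#' @return A list with elements `spectra` (raw spectra tibble, one row per
#'   scan) and `references` (the output of [simulate_references()]).
#' @examples
#' ds <- simulate_dataset(sim_config(n_eggs_per_class = 2, rotations_per_egg = 2))
#' nrow(ds$spectra) # 12
#' @export
simulate_dataset <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  rows <- list()
  egg_no <- 0L
  for (cls in 0:2) {
    cp <- cfg$class_params[[as.character(cls)]]
    for (i in seq_len(cfg$n_eggs_per_class)) {
      egg_no <- egg_no + 1L
      egg_id <- sprintf("egg_%03d", egg_no)
      # per-egg biological latent: chromophore amounts vary egg to egg
      conc <- with_seed(derive_seed(cfg$seed, "egg", cls, i), {
        vapply(cp$conc, function(mu) {
          if (mu > 0 && cfg$egg_sdlog > 0) rlnorm(1, log(mu), cfg$egg_sdlog) else mu
        }, numeric(1))
      })
      for (r in seq_len(cfg$rotations_per_egg)) {
        scan <- simulate_scan(cfg, cls, conc = conc,
                              seed = derive_seed(cfg$seed, "rot", cls, i, r))
        scan$egg_id <- egg_id
        scan$rotation <- r
        rows[[length(rows) + 1L]] <- scan
      }
    }
  }
  list(
    spectra = dplyr::bind_rows(rows),
    references = simulate_references(cfg)
  )
}
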