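# The band-reduction cascade: WRC + SFS + SPA on the beta-informative window,
# pooling, forward stepwise at a ladder of p-value thresholds, and a
# reduced-band PLS-DA refit + held-out evaluation per threshold.

# Fit a PLS-DA model on the given wavelengths and evaluate on held-out data.
fit_and_evaluate <- function(train, test, wavelengths, a_max = 10, folds = 10, seed = 1L) {
  tr <- select_bands(train, wavelengths)
  te <- select_bands(test, wavelengths)
  A <- choose_components(tr, A_max = min(a_max, length(wavelengths)),
                         folds = folds, seed = seed)
  model <- plsda_fit(tr, A)
  list(
    model = model,
    train_report = classification_report(tr$class, predict(model, tr)$.pred),
    test_report = classification_report(te$class, predict(model, te)$.pred)
  )
}

report_row <- function(rep) {
  pc <- rep$per_class
  acc <- function(cl) if (cl %in% pc$class) pc$accuracy[pc$class == cl] else NA_real_
  tibble(normal_acc = acc(0), bloody_acc = acc(1), yolk_acc = acc(2),
         total_acc = rep$total_accuracy)
}

#' Run the wavelength-selection cascade
#'
#' Restricts the training rows to the beta-informative selection window,
#' runs the three selectors (WRC peaks of the weighted regression
#' coefficient, sequential forward selection, successive projections), pools
#' their bands, filters the pool by forward stepwise regression at each
#' p-value threshold (plus a pass-through row keeping the whole pool), refits
#' a PLS-DA model per resulting band set and evaluates it on the held-out
#' rows.
#'
#' @param train,test Calibration and validation spectra tibbles (calibrated,
#'   preprocessed, on the modelling window).
#' @param selection_window Wavelength window (nm) in which the selectors
#'   operate; default `c(550, 600)`.
#' @param thresholds Stepwise entry thresholds, descending; default
#'   `c(0.05, 0.01, 0.001, 0.0001)`. A pass-through row (threshold 0) is
#'   always included first.
#' @param k_wrc,k_sfs,k_spa Band counts per selector (defaults 5, 3, 3).
#' @param sfs_folds CV folds inside the SFS criterion (default 5).
#' @param a_max Latent-variable cap for the full-window and reduced-band
#'   model fits (default 10).
#' @param seed Integer seed driving every internal split and fold draw.
#' @return An object of class `cascade_result`: `selections` (wrc, sfs, spa,
#'   pooled `selection_result`s), `stepwise` (one `selection_result` per
#'   threshold), `report` (tibble: threshold, n_bands, bands, per-class
#'   one-vs-rest accuracy and total validation accuracy), and `models`.
#' @export
run_cascade <- function(train, test,
                        selection_window = c(550, 600),
                        thresholds = c(0.05, 0.01, 0.001, 0.0001),
                        k_wrc = 5, k_sfs = 3, k_spa = 3,
                        sfs_folds = 5, a_max = 10, seed = 1L) {
  if (is.unsorted(rev(thresholds), strictly = TRUE)) {
    abort("thresholds must be strictly descending")
  }
  tr_sel <- restrict_range(train, selection_window[1], selection_window[2])

  # WRC needs a model on the selection window plus the mean spectrum there
  A_sel <- choose_components(tr_sel, A_max = a_max, seed = derive_seed(seed, "wrc_A"))
  model_sel <- plsda_fit(tr_sel, A_sel)
  wb <- weighted_beta(model_sel)
  wrc <- wrc_select(wb$weighted_beta, wb$wavelength,
                    colMeans(spectra_matrix(tr_sel)), k_max = k_wrc)
  sfs <- sfs_select(tr_sel, k = k_sfs, folds = sfs_folds, seed = derive_seed(seed, "sfs"))
  spa <- spa_select(tr_sel, k = k_spa, seed = derive_seed(seed, "spa"))
  pooled <- pool_bands(list(wrc, sfs, spa))

  tr_pool <- select_bands(train, pooled$wavelengths_nm)
  steps <- list()
  rows <- list()
  models <- list()
  for (thr in c(0, thresholds)) {
    sel <- stepwise_select(tr_pool, thr)
    key <- format(thr, scientific = FALSE)
    steps[[key]] <- sel
    fe <- fit_and_evaluate(train, test, sel$wavelengths_nm, a_max = a_max,
                           seed = derive_seed(seed, "refit", key))
    models[[key]] <- fe$model
    rows[[key]] <- dplyr::bind_cols(
      tibble(threshold = thr, n_bands = length(sel$wavelengths_nm),
             bands = paste(round(sel$wavelengths_nm), collapse = ", ")),
      report_row(fe$test_report)
    )
  }
  structure(
    list(
      selections = list(wrc = wrc, sfs = sfs, spa = spa, pooled = pooled),
      stepwise = steps,
      report = dplyr::bind_rows(rows),
      models = models,
      window_model = model_sel,
      selection_window = selection_window,
      seed = seed
    ),
    class = "cascade_result"
  )
}

#' @export
print.cascade_result <- function(x, ...) {
  cat("Wavelength-selection cascade\n")
  for (m in c("wrc", "sfs", "spa", "pooled")) {
    s <- x$selections[[m]]
    cat(sprintf("  %-7s %d band(s): %s\n", m, length(s$wavelengths_nm),
                paste(round(s$wavelengths_nm), collapse = ", ")))
  }
  cat("Reduced-band models (validation):\n")
  print(as.data.frame(x$report), row.names = FALSE)
  invisible(x)
}

#' @export
tidy.cascade_result <- function(x, ...) {
  x$report
}
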