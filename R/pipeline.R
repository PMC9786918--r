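# Config-driven orchestration of the full experimental grid:
# lamp x geometry condition x preprocessing, full-band PLS-DA per cell, best
# cell selection, and the band-reduction cascade on the best cell.

#' Build a pipeline run configuration
#'
#' @param lamps Subset of `c("silver", "gold")`.
#' @param conditions Subset of `c(1, 2, 3)`.
#' @param preprocessing Character vector of [preprocess_spec()] method names
#'   tried per cell (default `c("none", "mean_norm")`).
#' @param n_eggs_per_class,rotations_per_egg Design size (defaults 50 and 5).
#' @param axis Wavelength grid; default the full 2068-point 192--1110 nm axis.
#' @param modelling_window Wavelength window (nm) for the full-band models;
#'   default `c(500, 680)`.
#' @param selection_window Window for the band selectors; default
#'   `c(550, 600)`.
#' @param split_frac Calibration fraction (default 0.70).
#' @param thresholds Stepwise thresholds, descending (default
#'   `c(0.05, 0.01, 0.001, 0.0001)`).
#' @param k_wrc,k_sfs,k_spa Selector band counts (defaults 5, 3, 3).
#' @param a_max Latent-variable cap (default 15 for full-band models).
#' @param seed Integer master seed.
#' @param out_dir Output directory for report files, or `NULL` to skip
#'   writing.
#' @return A list of class `run_config`.
#' @export
run_config <- function(lamps = c("silver", "gold"),
                       conditions = c(1, 2, 3),
                       preprocessing = c("none", "mean_norm"),
                       n_eggs_per_class = 50,
                       rotations_per_egg = 5,
                       axis = seq(192, 1110, length.out = 2068),
                       modelling_window = c(500, 680),
                       selection_window = c(550, 600),
                       split_frac = 0.70,
                       thresholds = c(0.05, 0.01, 0.001, 0.0001),
                       k_wrc = 5, k_sfs = 3, k_spa = 3,
                       a_max = 15,
                       seed = 1L,
                       out_dir = NULL) {
  lamps <- match.arg(lamps, several.ok = TRUE)
  if (!all(conditions %in% 1:3)) abort("conditions must be within 1:3")
  stopifnot(modelling_window[1] < modelling_window[2],
            selection_window[1] < selection_window[2])
  if (is.unsorted(rev(thresholds), strictly = TRUE)) abort("thresholds must be descending")
  structure(
    list(lamps = lamps, conditions = conditions, preprocessing = preprocessing,
         n_eggs_per_class = n_eggs_per_class, rotations_per_egg = rotations_per_egg,
         axis = axis, modelling_window = modelling_window,
         selection_window = selection_window, split_frac = split_frac,
         thresholds = thresholds, k_wrc = k_wrc, k_sfs = k_sfs, k_spa = k_spa,
         a_max = a_max, seed = as.integer(seed), out_dir = out_dir),
    class = "run_config"
  )
}

#' Read a pipeline configuration from a YAML file
#'
#' Any field of [run_config()] may appear in the file; missing fields take
#' the defaults. `axis` may be given as `axis: {from: , to: , points: }`.
#'
#' @param path YAML file.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  if (!is.null(raw$axis) && is.list(raw$axis)) {
    raw$axis <- seq(raw$axis$from, raw$axis$to, length.out = raw$axis$points)
  }
  known <- names(formals(run_config))
  unknown <- setdiff(names(raw), known)
  if (length(unknown) > 0) abort(paste("unknown config fields:", paste(unknown, collapse = ", ")))
  do.call(run_config, raw)
}

# One lamp x condition cell: simulate, calibrate, restrict, split once, then
# fit a full-band model per preprocessing method.
run_cell <- function(config, lamp, condition) {
  cfg <- sim_config(
    axis = config$axis, lamp = lamp, condition = condition,
    n_eggs_per_class = config$n_eggs_per_class,
    rotations_per_egg = config$rotations_per_egg,
    seed = derive_seed(config$seed, "sim", lamp, condition)
  )
  ds <- simulate_dataset(cfg)
  trans <- calibrate(ds$spectra, ds$references)
  trans <- restrict_range(trans, config$modelling_window[1], config$modelling_window[2])
  split <- split_calibration_validation(trans, config$split_frac,
                                        seed = derive_seed(config$seed, "split", lamp, condition))
  rows <- list()
  fits <- list()
  for (method in config$preprocessing) {
    spec <- preprocess_fit(preprocess_spec(method), split$train)
    tr <- preprocess_apply(spec, split$train)
    te <- preprocess_apply(spec, split$test)
    A <- choose_components(tr, A_max = config$a_max,
                           seed = derive_seed(config$seed, "A", lamp, condition, method))
    model <- plsda_fit(tr, A)
    cal <- classification_report(tr$class, predict(model, tr)$.pred)
    val <- classification_report(te$class, predict(model, te)$.pred)
    rows[[method]] <- dplyr::bind_cols(
      tibble(lamp = lamp, condition = condition, preprocessing = method,
             n_components = model$A, cal_total_acc = cal$total_accuracy),
      report_row(val)
    )
    fits[[method]] <- list(spec = spec, train = tr, test = te, model = model)
  }
  list(rows = dplyr::bind_rows(rows), fits = fits,
       n_spectra = nrow(ds$spectra), n_train = nrow(split$train), n_test = nrow(split$test))
}

#' Run the full analysis pipeline
#'
#' For every lamp x condition cell: generate a synthetic dataset, calibrate
#' to transmittance, restrict to the modelling window, split once into
#' calibration/validation, and fit a full-band PLS-DA model per preprocessing
#' method. The cell/preprocessing combination with the best validation
#' accuracy is then fed to the band-reduction cascade. If `out_dir` is set,
#' report CSVs (full-band models, selected bands, stepwise bands,
#' reduced-band models, beta curves) and a JSON summary are written; rerunning
#' with the same config and seed reproduces them byte for byte.
#'
#' @param config A [run_config()].
#' @return An object of class `pipeline_result`: `full_band` (tibble of all
#'   full-band models), `best` (lamp, condition, preprocessing), `cascade`
#'   (a `cascade_result`), `counts`, and `files` (paths written, if any).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  cells <- list()
  full_rows <- list()
  counts <- list()
  for (lamp in config$lamps) {
    for (condition in config$conditions) {
      key <- paste(lamp, condition, sep = "_")
      t0 <- Sys.time()
      cell <- tryCatch(run_cell(config, lamp, condition), error = function(e) e)
      if (inherits(cell, "error")) {
        warn(sprintf("cell %s aborted: %s", key, conditionMessage(cell)))
        next
      }
      message(sprintf("[eggspec] cell %s: %d spectra, %d/%d split (%.1fs)",
                      key, cell$n_spectra, cell$n_train, cell$n_test,
                      as.numeric(difftime(Sys.time(), t0, units = "secs"))))
      cells[[key]] <- cell
      full_rows[[key]] <- cell$rows
      counts[[key]] <- list(n_spectra = cell$n_spectra, n_train = cell$n_train,
                            n_test = cell$n_test)
    }
  }
  if (length(full_rows) == 0L) abort("every cell failed")
  full_band <- dplyr::bind_rows(full_rows)
  best_i <- which.max(full_band$total_acc)
  best <- full_band[best_i, c("lamp", "condition", "preprocessing")]
  best_fit <- cells[[paste(best$lamp, best$condition, sep = "_")]]$fits[[best$preprocessing]]
  message(sprintf("[eggspec] best cell: %s condition %d, %s (validation %.1f%%)",
                  best$lamp, best$condition, best$preprocessing,
                  full_band$total_acc[best_i]))
  cascade <- run_cascade(
    best_fit$train, best_fit$test,
    selection_window = config$selection_window,
    thresholds = config$thresholds,
    k_wrc = config$k_wrc, k_sfs = config$k_sfs, k_spa = config$k_spa,
    a_max = min(config$a_max, 10),
    seed = derive_seed(config$seed, "cascade")
  )
  result <- structure(
    list(full_band = full_band, best = best, cascade = cascade,
         best_fit = best_fit, counts = counts, config = config, files = character(0)),
    class = "pipeline_result"
  )
  if (!is.null(config$out_dir)) result <- write_pipeline_reports(result, config$out_dir)
  result
}

write_pipeline_reports <- function(result, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(
    full_band = file.path(out_dir, "full_band_models.csv"),
    selected = file.path(out_dir, "selected_bands.csv"),
    stepwise = file.path(out_dir, "stepwise_bands.csv"),
    reduced = file.path(out_dir, "reduced_band_models.csv"),
    beta = file.path(out_dir, "beta_curves.csv"),
    summary = file.path(out_dir, "summary.json")
  )
  readr::write_csv(result$full_band, paths[["full_band"]])
  sel <- dplyr::bind_rows(lapply(result$cascade$selections, tidy))
  readr::write_csv(sel, paths[["selected"]])
  stepw <- dplyr::bind_rows(lapply(names(result$cascade$stepwise), function(k) {
    s <- result$cascade$stepwise[[k]]
    tibble(threshold = as.numeric(k), n_bands = length(s$wavelengths_nm),
           wavelength = s$wavelengths_nm)
  }))
  readr::write_csv(stepw, paths[["stepwise"]])
  readr::write_csv(result$cascade$report, paths[["reduced"]])
  beta <- dplyr::bind_rows(c(
    list(window = dplyr::mutate(weighted_beta(result$cascade$window_model), model = "selection_window")),
    lapply(names(result$cascade$models), function(k) {
      dplyr::mutate(weighted_beta(result$cascade$models[[k]]), model = paste0("threshold_", k))
    })
  ))
  readr::write_csv(beta, paths[["beta"]])
  summary <- list(
    seed = result$config$seed,
    config_hash = rlang::hash(result$config),
    best = as.list(result$best),
    counts = result$counts,
    full_band_models = nrow(result$full_band),
    reduced_band_models = nrow(result$cascade$report)
  )
  jsonlite::write_json(summary, paths[["summary"]], auto_unbox = TRUE, pretty = TRUE)
  result$files <- paths
  result
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("eggspec pipeline result\n\nFull-band models:\n")
  print(as.data.frame(x$full_band), row.names = FALSE)
  cat(sprintf("\nBest cell: %s condition %d, %s\n\n",
              x$best$lamp, x$best$condition, x$best$preprocessing))
  print(x$cascade)
  invisible(x)
}
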