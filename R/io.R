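# CSV I/O for spectra tables. Dialect: one scan per row, header
# egg_id,class,lamp,condition,rotation[,kind],<wavelengths printed at 2 dp>.
# References: 2-row CSV with a `ref` column (white, dark) on the same axis.

#' Write a spectra tibble to CSV
#'
#' @param df Spectra tibble (metadata columns + wavelength columns).
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_spectra <- function(df, path) {
  readr::write_csv(df, path)
  invisible(path)
}

#' Read a spectra tibble from CSV
#'
#' Wavelength columns are recognised by their numeric names; all other
#' columns are carried as metadata.
#'
#' @param path CSV file written by [write_spectra()] (or with the same
#'   layout).
#' @return A spectra tibble.
#' @export
read_spectra <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE,
                        name_repair = "minimal")
  check_axis(spectra_axis(df))
  df
}

#' Write calibration references to CSV
#'
#' @param refs Two-row tibble from [simulate_references()] (`ref` column plus
#'   wavelength columns).
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_references <- function(refs, path) {
  readr::write_csv(refs, path)
  invisible(path)
}

#' Read calibration references from CSV
#'
#' @param path CSV file with rows `white` and `dark`.
#' @return Two-row references tibble.
#' @export
read_references <- function(path) {
  refs <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE,
                          name_repair = "minimal")
  if (!all(c("white", "dark") %in% refs$ref)) {
    abort("references file must contain rows 'white' and 'dark'")
  }
  refs
}
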