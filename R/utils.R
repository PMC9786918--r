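# Internal helpers shared across modules: seeded RNG scoping, wavelength-column
# bookkeeping for the wide spectra tibble, and small validators.

# Evaluate `expr` under a fixed RNG seed without disturbing the caller's
# RNG stream. All randomness in the package flows through this helper so a
# single integer seed makes every artifact reproducible.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else {
      NULL
    }
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(as.integer(seed))
  }
  force(expr)
}

# Derive a child seed from a parent seed and a stream label, so independent
# stages (dataset cells, references, splits) never share an RNG stream.
# Plain 32-bit-safe integer hashing; stays in [0, 2^31 - 2].
derive_seed <- function(seed, ...) {
  labels <- paste(c(seed, ...), collapse = "/")
  bytes <- utf8ToInt(labels)
  h <- 0
  for (b in bytes) h <- (h * 31 + b) %% 2147483629
  as.integer(h)
}

#' Identify wavelength columns of a spectra tibble
#'
#' Spectra tibbles are wide: metadata columns (`egg_id`, `class`, `lamp`,
#' `condition`, `rotation`, `kind`, ...) followed by one numeric-named column
#' per wavelength in nm. A column is a wavelength column iff its name parses
#' as a finite number.
#'
#' @param df A spectra tibble.
#' @return Character vector of wavelength column names, in table order.
#' @export
wl_cols <- function(df) {
  nm <- names(df)
  nm[!is.na(suppressWarnings(as.numeric(nm)))]
}

#' Wavelength axis of a spectra tibble
#'
#' @param df A spectra tibble (see [wl_cols()]).
#' @return Numeric vector of wavelengths (nm), in column order.
#' @export
spectra_axis <- function(df) {
  as.numeric(wl_cols(df))
}

#' Intensity matrix of a spectra tibble
#'
#' @param df A spectra tibble.
#' @return Numeric matrix, rows = scans, columns = wavelengths.
#' @export
spectra_matrix <- function(df) {
  cols <- wl_cols(df)
  if (length(cols) == 0L) abort("no wavelength columns found")
  m <- as.matrix(df[, cols, drop = FALSE])
  storage.mode(m) <- "double"
  dimnames(m) <- list(NULL, cols)
  m
}

#' Metadata columns of a spectra tibble
#'
#' @param df A spectra tibble.
#' @return Tibble of the non-wavelength columns.
#' @export
spectra_meta <- function(df) {
  as_tibble(df[, setdiff(names(df), wl_cols(df)), drop = FALSE])
}

# Rebuild a spectra tibble from metadata + matrix + axis.
build_spectra <- function(meta, mat, axis) {
  stopifnot(nrow(meta) == nrow(mat), length(axis) == ncol(mat))
  colnames(mat) <- format_axis(axis)
  dplyr::bind_cols(meta, as_tibble(mat, .name_repair = "minimal"))
}

# Canonical printing of wavelengths as column names: 2 decimal places.
format_axis <- function(axis) {
  sprintf("%.2f", axis)
}

check_axis <- function(axis) {
  if (length(axis) < 1L || anyNA(axis)) abort("axis must be non-empty and free of NA")
  if (length(axis) > 1L && any(diff(axis) <= 0)) abort("axis must be strictly increasing")
  invisible(axis)
}

# Shared axis check for operations combining several spectra tables.
check_same_axis <- function(a, b, what = "spectra") {
  if (length(a) != length(b) || any(abs(a - b) > 1e-9)) {
    abort(paste0("wavelength axes of ", what, " do not match"))
  }
  invisible(TRUE)
}
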