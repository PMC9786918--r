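# Wavelength (band) selection: weighted-regression-coefficient peak picking,
# sequential forward selection, the successive projections algorithm, pooling,
# and forward stepwise regression gated by the partial-F p-value.

selection_result <- function(method, wavelengths, indices, trace, ...) {
  ord <- order(wavelengths)
  structure(
    list(method = method,
         wavelengths_nm = wavelengths[ord],
         indices = indices[ord],
         trace = trace,
         ...),
    class = "selection_result"
  )
}

#' @export
print.selection_result <- function(x, ...) {
  cat(sprintf("<selection_result: %s> %d band(s): %s\n", x$method,
              length(x$wavelengths_nm),
              paste(round(x$wavelengths_nm), collapse = ", ")))
  invisible(x)
}

#' @export
tidy.selection_result <- function(x, ...) {
  tibble(method = x$method, wavelength = x$wavelengths_nm, index = x$indices)
}

# Local maxima of |v|: points strictly greater than both neighbours, with
# plateaus (runs of equal values above both flanks) collapsed to their center.
# Endpoints are never peaks.
find_peaks <- function(v) {
  r <- rle(v)
  k <- length(r$values)
  if (k < 3L) return(integer(0))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  peaks <- integer(0)
  for (i in 2:(k - 1L)) {
    if (r$values[i] > r$values[i - 1L] && r$values[i] > r$values[i + 1L]) {
      peaks <- c(peaks, starts[i] + (r$lengths[i] - 1L) %/% 2L)
    }
  }
  peaks
}

#' Select bands from weighted regression coefficient peaks
#'
#' Finds the local maxima of the absolute weighted (autoscaled) regression
#' coefficient and ranks them by `|wbeta| * mean spectral intensity`, so a
#' high coefficient in a region of negligible transmitted light does not win;
#' the top `k_max` peaks are returned.
#'
#' @param wbeta Weighted regression coefficients aligned to `axis` (e.g.
#'   column `weighted_beta` of [weighted_beta()]).
#' @param axis Wavelengths (nm).
#' @param intensity_mean Mean training spectrum on the same axis.
#' @param k_max Maximum number of bands (default 5).
#' @return A `selection_result` (method `"wrc"`); the trace records each
#'   peak's ranking criterion.
#' @export
wrc_select <- function(wbeta, axis, intensity_mean, k_max = 5) {
  stopifnot(length(wbeta) == length(axis), length(intensity_mean) == length(axis), k_max >= 1)
  v <- abs(wbeta)
  peaks <- find_peaks(v)
  if (length(peaks) == 0L) abort("wrc_select: no interior peaks in |weighted beta|")
  crit <- v[peaks] * intensity_mean[peaks]
  ord <- order(crit, decreasing = TRUE)
  take <- peaks[ord][seq_len(min(k_max, length(peaks)))]
  trace <- tibble(step = seq_along(ord), index = peaks[ord],
                  wavelength = axis[peaks[ord]], criterion = crit[ord],
                  selected = seq_along(ord) <= min(k_max, length(peaks)))
  selection_result("wrc", axis[take], take, trace)
}

# Lean k-fold CV misclassification of a PLS1 discriminant model on a column
# subset; fold assignment fixed by the caller so candidates are comparable.
cv_misclass <- function(X, y, fold_id) {
  n <- nrow(X)
  wrong <- 0L
  for (f in unique(fold_id)) {
    tr <- fold_id != f
    Xtr <- X[tr, , drop = FALSE]
    A <- min(ncol(X), sum(tr) - 1L)
    mu <- colMeans(Xtr)
    sds <- apply(Xtr, 2, sd)
    if (any(sds == 0)) return(Inf)
    ym <- mean(y[tr])
    fit <- tryCatch(pls1_nipals(sweep(Xtr, 2, mu), y[tr] - ym, A),
                    error = function(e) NULL)
    if (is.null(fit)) return(Inf)
    beta <- drop(fit$R %*% fit$q)
    score <- drop(sweep(X[!tr, , drop = FALSE], 2, mu) %*% beta) + ym
    wrong <- wrong + sum(score_to_class(score) != y[!tr])
  }
  wrong / n
}

#' Sequential forward selection of wavelengths
#'
#' Greedy forward search: starting from the empty set, each step adds the
#' wavelength that minimises the cross-validated misclassification rate of a
#' PLS-DA model on the current set plus that candidate, stopping at `k`
#' wavelengths. Ties break toward the lower wavelength. Fold assignment is
#' drawn once from `seed` and shared by every candidate evaluation, so the
#' trace is fully reproducible.
#'
#' @param train Training spectra tibble with a `class` column.
#' @param k Number of wavelengths to select (default 3).
#' @param folds CV folds (default 5).
#' @param seed Integer seed for the fold assignment.
#' @return A `selection_result` (method `"sfs"`); the trace records the CV
#'   misclassification of the winning candidate at each step.
#' @export
sfs_select <- function(train, k = 3, folds = 5, seed = 1L) {
  X <- spectra_matrix(train)
  axis <- spectra_axis(train)
  y <- as.numeric(train$class)
  if (k > ncol(X)) abort("k exceeds the number of wavelengths")
  n <- nrow(X)
  fold_id <- with_seed(derive_seed(seed, "sfs_folds"), sample(rep_len(seq_len(min(folds, n)), n)))
  selected <- integer(0)
  trace <- list()
  for (step in seq_len(k)) {
    cand <- setdiff(seq_len(ncol(X)), selected)
    errs <- vapply(cand, function(j) cv_misclass(X[, c(selected, j), drop = FALSE], y, fold_id),
                   numeric(1))
    # ties toward the lower wavelength: candidates are in ascending axis order
    best <- cand[which.min(errs)]
    selected <- c(selected, best)
    trace[[step]] <- tibble(step = step, index = best, wavelength = axis[best],
                            criterion = min(errs))
  }
  selection_result("sfs", axis[selected], selected, dplyr::bind_rows(trace))
}

# Literal successive-projection chain from one start column. `Vc` is the
# mean-centered matrix; returns selected indices and per-step projected norms.
spa_chain <- function(Vc, start, k) {
  p <- ncol(Vc)
  V <- Vc
  selected <- start
  norms <- sqrt(sum(V[, start]^2))
  for (step in seq_len(k - 1L)) {
    s <- selected[length(selected)]
    vs <- V[, s]
    denom <- sum(vs^2)
    if (denom < 1e-24) break
    # project every column onto the orthogonal complement of the selected span
    V <- V - vs %*% t(drop(crossprod(vs, V)) / denom)
    cand <- setdiff(seq_len(p), selected)
    cn <- sqrt(colSums(V[, cand, drop = FALSE]^2))
    if (max(cn) < 1e-12) {
      attr(selected, "early_stop") <- step
      break
    }
    best <- cand[which.max(cn)]
    selected <- c(selected, best)
    norms <- c(norms, max(cn))
  }
  list(indices = selected, norms = norms)
}

#' Successive projections algorithm
#'
#' Collinearity-minimising selection: from each possible start column a chain
#' is grown by repeatedly projecting all remaining columns onto the orthogonal
#' complement of the selected span and taking the column of maximum projected
#' norm. Among all start chains, the one whose `k` columns give the lowest
#' misclassification of a PLS-DA model on an internal seeded 70/30 split of
#' the training rows is returned.
#'
#' @param train Training spectra tibble with a `class` column; columns are
#'   mean-centered internally before the projections.
#' @param k Number of wavelengths (default 3).
#' @param seed Integer seed for the internal chain-scoring split.
#' @return A `selection_result` (method `"spa"`); the trace records the
#'   projected norm at each step of the winning chain, and `chain_scores`
#'   holds the internal misclassification of every start.
#' @export
spa_select <- function(train, k = 3, seed = 1L) {
  X <- spectra_matrix(train)
  axis <- spectra_axis(train)
  y <- as.numeric(train$class)
  if (k > min(nrow(X) - 1L, ncol(X))) abort("k exceeds min(n - 1, p)")
  Vc <- sweep(X, 2, colMeans(X))
  chains <- lapply(seq_len(ncol(X)), function(s) spa_chain(Vc, s, k))
  split <- split_calibration_validation(train, 0.70, seed = derive_seed(seed, "spa_split"))
  Xtr <- spectra_matrix(split$train); Xte <- spectra_matrix(split$test)
  ytr <- as.numeric(split$train$class); yte <- as.numeric(split$test$class)
  score_chain <- function(idx) {
    if (length(idx) < k) return(Inf)
    Xs <- Xtr[, idx, drop = FALSE]
    mu <- colMeans(Xs)
    if (any(apply(Xs, 2, sd) == 0)) return(Inf)
    fit <- tryCatch(pls1_nipals(sweep(Xs, 2, mu), ytr - mean(ytr), min(k, nrow(Xs) - 1L)),
                    error = function(e) NULL)
    if (is.null(fit)) return(Inf)
    beta <- drop(fit$R %*% fit$q)
    pred <- score_to_class(drop(sweep(Xte[, idx, drop = FALSE], 2, mu) %*% beta) + mean(ytr))
    mean(pred != yte)
  }
  scores <- vapply(chains, function(ch) score_chain(ch$indices), numeric(1))
  if (all(!is.finite(scores))) abort("spa_select: no start chain reached k usable columns")
  best <- which.min(scores) # ties: lowest start wavelength
  ch <- chains[[best]]
  trace <- tibble(step = seq_along(ch$indices), index = ch$indices,
                  wavelength = axis[ch$indices], criterion = ch$norms)
  selection_result("spa", axis[ch$indices], ch$indices, trace,
                   chain_scores = tibble(start_wavelength = axis, misclass = scores))
}

#' Pool band sets from several selectors
#'
#' Sorted, de-duplicated union of the selected wavelengths.
#'
#' @param results List of `selection_result` objects from the same axis.
#' @return A `selection_result` with method `"pooled"`.
#' @export
pool_bands <- function(results) {
  if (length(results) == 0L) abort("pool_bands: empty input")
  idx <- sort(unique(unlist(lapply(results, `[[`, "indices"))))
  wl <- sort(unique(unlist(lapply(results, `[[`, "wavelengths_nm"))))
  trace <- dplyr::bind_rows(lapply(results, function(r) {
    tibble(method = r$method, wavelength = r$wavelengths_nm, index = r$indices)
  }))
  selection_result("pooled", wl, idx, trace)
}

# RSS of OLS with intercept on columns `idx` of X (empty idx = intercept only).
ols_rss <- function(X, y, idx) {
  if (length(idx) == 0L) return(sum((y - mean(y))^2))
  M <- cbind(1, X[, idx, drop = FALSE])
  fit <- lm.fit(M, y)
  sum(fit$residuals^2)
}

#' Forward stepwise selection by partial-F p-value
#'
#' Forward-only stepwise regression of the numeric class label on the pooled
#' bands: at each step the partial-F p-value of every unselected candidate
#' (added to the current ordinary-least-squares model) is computed, and the
#' candidate with the smallest p-value enters if that p-value is below
#' `p_enter`; otherwise selection stops. Because entry is forward-only, band
#' sets at stricter thresholds are nested inside those at looser ones.
#' `p_enter = 0` is a pass-through sentinel returning the input set unchanged.
#'
#' @param train Training spectra tibble (already restricted to the pooled
#'   bands) with a `class` column.
#' @param p_enter Entry threshold in (0, 1), or 0 for pass-through.
#' @return A `selection_result` (method `"stepwise"`); the trace records the
#'   partial-F p-value of every candidate at every step.
#' @export
stepwise_select <- function(train, p_enter) {
  X <- spectra_matrix(train)
  axis <- spectra_axis(train)
  y <- as.numeric(train$class)
  if (ncol(X) == 0L) abort("stepwise_select: empty band set")
  if (p_enter == 0) {
    return(selection_result("stepwise", axis, seq_len(ncol(X)),
                            tibble(step = integer(0), index = integer(0),
                                   wavelength = numeric(0), p_value = numeric(0),
                                   selected = logical(0)),
                            p_enter = 0, note = "pass-through"))
  }
  if (!(p_enter > 0 && p_enter < 1)) abort("p_enter must be in (0, 1), or 0 for pass-through")
  n <- nrow(X)
  selected <- integer(0)
  trace <- list()
  repeat {
    cand <- setdiff(seq_len(ncol(X)), selected)
    if (length(cand) == 0L) break
    if (n <= length(selected) + 2L) {
      trace[[length(trace) + 1L]] <- tibble(step = length(selected) + 1L, index = NA_integer_,
                                            wavelength = NA_real_, p_value = NA_real_,
                                            selected = FALSE)
      warn("stepwise_select stopped early: too few rows for another term")
      break
    }
    rss0 <- ols_rss(X, y, selected)
    df2 <- n - length(selected) - 2L # intercept + selected + candidate
    pvals <- vapply(cand, function(j) {
      rss1 <- ols_rss(X, y, c(selected, j))
      f <- (rss0 - rss1) / (rss1 / df2)
      pf(f, 1, df2, lower.tail = FALSE)
    }, numeric(1))
    step <- length(selected) + 1L
    trace[[length(trace) + 1L]] <- tibble(step = step, index = cand,
                                          wavelength = axis[cand], p_value = pvals,
                                          selected = FALSE)
    best <- which.min(pvals) # ties toward the lower wavelength (ascending order)
    if (pvals[best] < p_enter) {
      trace[[length(trace)]]$selected[best] <- TRUE
      selected <- c(selected, cand[best])
    } else {
      break
    }
  }
  if (length(selected) == 0L) {
    abort("stepwise_select: no candidate passed the entry threshold")
  }
  selection_result("stepwise", axis[selected], selected, dplyr::bind_rows(trace),
                   p_enter = p_enter)
}

#' Keep only the given wavelengths of a spectra tibble
#'
#' @param df Spectra tibble.
#' @param wavelengths_nm Wavelengths to keep (matched exactly against the
#'   axis, tolerance 1e-6 nm).
#' @return Spectra tibble restricted to those wavelength columns.
#' @export
select_bands <- function(df, wavelengths_nm) {
  axis <- spectra_axis(df)
  idx <- vapply(wavelengths_nm, function(w) {
    j <- which(abs(axis - w) < 1e-6)
    if (length(j) != 1L) abort(sprintf("wavelength %.4f nm not on the axis", w))
    j
  }, integer(1))
  idx <- sort(idx)
  build_spectra(spectra_meta(df), spectra_matrix(df)[, idx, drop = FALSE], axis[idx])
}
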