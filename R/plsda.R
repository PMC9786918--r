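# Three-class PLS-DA on the numeric class coding 0 = normal, 1 = bloody,
# 2 = yolk-destroyed: single-response (PLS1) NIPALS on column-centered X and
# centered y, nearest-label assignment at thresholds 0.5 and 1.5.

#' Build a spectra tibble from a plain matrix
#'
#' Convenience constructor for modelling and testing: wraps a numeric matrix
#' as a spectra tibble with the standard metadata columns.
#'
#' @param X Numeric matrix, rows = scans.
#' @param axis Wavelengths (nm) for the columns; defaults to `1:ncol(X)`.
#' @param class Optional integer class labels (0/1/2), recycled to `nrow(X)`.
#' @return A spectra tibble.
#' @export
as_spectra <- function(X, axis = seq_len(ncol(X)), class = NA_integer_) {
  X <- as.matrix(X)
  check_axis(axis)
  meta <- tibble(
    egg_id = sprintf("row_%03d", seq_len(nrow(X))),
    class = as.integer(rep_len(class, nrow(X))),
    lamp = NA_character_, condition = NA_integer_,
    rotation = NA_integer_, kind = "transmittance"
  )
  build_spectra(meta, X, axis)
}

#' Stratified calibration/validation split
#'
#' Randomly assigns `floor(frac * n_class)` rows of each class to the
#' calibration (training) set and the remainder to the validation set,
#' reproducibly from `seed`.
#'
#' @param df Spectra tibble with a `class` column.
#' @param frac Training fraction, strictly between 0 and 1 (default 0.70).
#' @param seed Integer seed.
#' @return List with elements `train` and `test`.
#' @export
split_calibration_validation <- function(df, frac = 0.70, seed = 1L) {
  if (!(frac > 0 && frac < 1)) abort("frac must be in (0, 1)")
  if (!"class" %in% names(df)) abort("df needs a class column")
  counts <- table(df$class)
  if (any(counts < 2)) abort("every class needs at least 2 rows to split")
  idx_train <- with_seed(seed, {
    unlist(lapply(sort(unique(df$class)), function(cl) {
      rows <- which(df$class == cl)
      sample(rows, floor(frac * length(rows)))
    }), use.names = FALSE)
  })
  idx_train <- sort(idx_train)
  list(train = df[idx_train, , drop = FALSE],
       test = df[-idx_train, , drop = FALSE])
}

# NIPALS PLS1 on centered X, centered y. Returns weights W, scores T,
# loadings P, y-loadings q (one scalar per component), residuals, and the
# projection weights R = W (P'W)^{-1} from which beta for any number of
# components is R[, 1:a] %*% q[1:a].
pls1_nipals <- function(Xc, yc, A) {
  n <- nrow(Xc); p <- ncol(Xc)
  W <- P <- matrix(0, p, A)
  Tm <- matrix(0, n, A)
  q <- numeric(A)
  Xr <- Xc; yr <- yc
  a_used <- 0L
  for (a in seq_len(A)) {
    w <- drop(crossprod(Xr, yr))
    nw <- sqrt(sum(w^2))
    if (nw < 1e-12) break # no covariance left
    w <- w / nw
    # sign convention: first nonzero weight positive, for stable comparisons
    nz <- which(abs(w) > 1e-12)[1]
    if (w[nz] < 0) w <- -w
    t_ <- drop(Xr %*% w)
    tt <- sum(t_^2)
    if (tt < 1e-24) break
    p_ <- drop(crossprod(Xr, t_)) / tt
    q_ <- sum(yr * t_) / tt
    Xr <- Xr - tcrossprod(t_, p_)
    yr <- yr - t_ * q_
    W[, a] <- w; P[, a] <- p_; Tm[, a] <- t_; q[a] <- q_
    a_used <- a
  }
  if (a_used == 0L) abort("PLS fit failed: X carries no covariance with y")
  keep <- seq_len(a_used)
  W <- W[, keep, drop = FALSE]; P <- P[, keep, drop = FALSE]
  Tm <- Tm[, keep, drop = FALSE]; q <- q[keep]
  R <- W %*% solve(crossprod(P, W))
  list(W = W, P = P, T = Tm, q = q, R = R, E = Xr, F = yr, A = a_used)
}

#' Fit a PLS-DA model
#'
#' Single-response NIPALS partial least squares on column-centered spectra
#' and the centered numeric class label, used as a three-class discriminant
#' model (labels 0, 1, 2; thresholds 0.5 and 1.5).
#'
#' @param train Training spectra tibble with a `class` column and no missing
#'   values in the wavelength columns.
#' @param A Number of latent variables, `1 <= A <= min(n - 1, p)`.
#' @return An object of class `plsda`: scores `T`, X-loadings `P`, Y-scores
#'   `U`, Y-loadings `Q`, residuals `E` and `F`, regression vector `beta`
#'   (centered-X to centered-y scale), training column means/sds, class
#'   thresholds, and the wavelength axis.
#' @export
plsda_fit <- function(train, A) {
  X <- spectra_matrix(train)
  if (anyNA(X)) abort("training spectra contain missing values; restrict_range() first")
  y <- as.numeric(train$class)
  if (!all(y %in% 0:2)) abort("class labels must be coded 0, 1, 2")
  n <- nrow(X); p <- ncol(X)
  if (!(A >= 1 && A <= min(n - 1, p))) abort("A must satisfy 1 <= A <= min(n - 1, p)")
  x_means <- colMeans(X)
  x_sds <- apply(X, 2, sd)
  if (any(x_sds == 0)) abort("zero-variance wavelength column in training data")
  Xc <- sweep(X, 2, x_means)
  y_mean <- mean(y)
  yc <- y - y_mean
  fit <- pls1_nipals(Xc, yc, A)
  if (fit$A < A) {
    warn(sprintf("PLS stopped at %d of %d requested components (no covariance left)", fit$A, A))
  }
  beta <- drop(fit$R %*% fit$q)
  structure(
    list(
      A = fit$A, T = fit$T, P = fit$P, U = fit$T, Q = fit$q,
      E = fit$E, F = fit$F, W = fit$W, R = fit$R, beta = beta,
      x_means = x_means, x_sds = x_sds, y_mean = y_mean,
      thresholds = c(0.5, 1.5), axis = spectra_axis(train),
      n = n, p = p
    ),
    class = "plsda"
  )
}

# beta using only the first `a` latent variables.
beta_for <- function(model, a) {
  a <- min(a, model$A)
  drop(model$R[, seq_len(a), drop = FALSE] %*% model$Q[seq_len(a)])
}

# Continuous score -> class label: 0 below 0.5, 1 in [0.5, 1.5), 2 at or
# above 1.5 (nearest label; boundaries belong to the upper interval).
score_to_class <- function(score, thresholds = c(0.5, 1.5)) {
  ifelse(score < thresholds[1], 0L, ifelse(score < thresholds[2], 1L, 2L))
}

#' Predict class scores and labels
#'
#' @param object A fitted [plsda_fit()] model.
#' @param newdata Spectra tibble on the model's wavelength axis.
#' @param A Number of latent variables to use (default: all fitted).
#' @param ... Unused.
#' @return The metadata of `newdata` with columns `.score` (continuous PLS
#'   prediction on the 0--2 label scale) and `.pred` (assigned class).
#' @export
predict.plsda <- function(object, newdata, A = object$A, ...) {
  X <- spectra_matrix(newdata)
  if (ncol(X) != object$p) abort("newdata has a different number of wavelengths than training")
  check_same_axis(spectra_axis(newdata), object$axis, "newdata and model")
  if (anyNA(X)) abort("newdata contains missing values")
  beta <- beta_for(object, A)
  score <- drop(sweep(X, 2, object$x_means) %*% beta) + object$y_mean
  out <- spectra_meta(newdata)
  out$.score <- score
  out$.pred <- score_to_class(score, object$thresholds)
  out
}

#' Choose the number of latent variables by cross-validation
#'
#' K-fold cross-validated misclassification over `A = 1, ..., A_max`. The
#' returned `A*` is the smallest A whose CV error is within one standard
#' error of the minimum (so ties and noise-level differences resolve toward
#' the simpler model).
#'
#' @param train Training spectra tibble with a `class` column.
#' @param A_max Largest number of latent variables to consider (default 20;
#'   capped by the fold dimensions).
#' @param folds Number of CV folds (default 10).
#' @param seed Integer seed for the fold assignment.
#' @return Integer `A*`.
#' @export
choose_components <- function(train, A_max = 20, folds = 10, seed = 1L) {
  X <- spectra_matrix(train)
  n <- nrow(X)
  folds <- min(folds, n)
  fold_id <- with_seed(derive_seed(seed, "cv_folds"), sample(rep_len(seq_len(folds), n)))
  A_max <- min(A_max, ncol(X), n - ceiling(n / folds) - 1)
  if (A_max < 1) A_max <- 1
  miss <- numeric(A_max)
  for (f in seq_len(folds)) {
    tr <- train[fold_id != f, , drop = FALSE]
    te <- train[fold_id == f, , drop = FALSE]
    a_fit <- min(A_max, nrow(tr) - 1)
    m <- plsda_fit(tr, a_fit)
    for (a in seq_len(A_max)) {
      pred <- predict(m, te, A = min(a, m$A))
      miss[a] <- miss[a] + sum(pred$.pred != te$class)
    }
  }
  err <- miss / n
  emin <- min(err)
  se <- sqrt(emin * (1 - emin) / n)
  as.integer(which(err <= emin + se)[1])
}

#' Classification report: confusion matrix, accuracy, recall, precision
#'
#' One-vs-rest true/false positive/negative counts per class, per-class
#' accuracy `(Tp + Tn) / (Tp + Tn + Fp + Fn) * 100`, recall
#' `Tp / (Tp + Fn) * 100` and precision `Tp / (Tp + Fp) * 100`, plus the
#' total accuracy (share of rows whose label matches the truth). Undefined
#' ratios (zero denominator) are reported as `NA`, never as 0.
#'
#' @param truth Integer vector of true class labels.
#' @param estimate Integer vector of predicted labels, same length.
#' @return A list of class `classification_report` with elements `confusion`
#'   (table, truth in rows), `per_class` (tibble with counts and the three
#'   percentages per class), `total_accuracy` (percent) and `n`.
#' @export
classification_report <- function(truth, estimate) {
  if (length(truth) == 0L) abort("empty input")
  if (length(truth) != length(estimate)) abort("truth and estimate lengths differ")
  levels <- sort(unique(c(truth, estimate)))
  conf <- table(truth = factor(truth, levels), estimate = factor(estimate, levels))
  n <- length(truth)
  per_class <- purrr::map_dfr(levels, function(cl) {
    tp <- sum(truth == cl & estimate == cl)
    fn <- sum(truth == cl & estimate != cl)
    fp <- sum(truth != cl & estimate == cl)
    tn <- sum(truth != cl & estimate != cl)
    tibble(
      class = cl, tp = tp, tn = tn, fp = fp, fn = fn,
      accuracy = 100 * (tp + tn) / n,
      recall = if (tp + fn > 0) 100 * tp / (tp + fn) else NA_real_,
      precision = if (tp + fp > 0) 100 * tp / (tp + fp) else NA_real_
    )
  })
  structure(
    list(
      confusion = conf,
      per_class = per_class,
      total_accuracy = 100 * sum(truth == estimate) / n,
      n = n
    ),
    class = "classification_report"
  )
}

#' @export
print.classification_report <- function(x, ...) {
  cat(sprintf("Classification report (n = %d, total accuracy %.1f%%)\n", x$n, x$total_accuracy))
  print(x$confusion)
  print(x$per_class)
  invisible(x)
}

#' Weighted (autoscaled) regression coefficients
#'
#' Rescales the PLS regression vector by each wavelength's training standard
#' deviation: `wbeta_j = beta_j * sd_j`. This equals (up to one positive
#' constant) the coefficient vector of a refit on autoscaled spectra, and is
#' the ranking signal of the weighted-regression-coefficient band selector.
#' Zero-variance columns are flagged `NA`.
#'
#' @param model A fitted [plsda_fit()] model.
#' @return Tibble with columns `wavelength`, `beta`, `sd`, `weighted_beta`.
#' @export
weighted_beta <- function(model) {
  stopifnot(inherits(model, "plsda"))
  wb <- model$beta * model$x_sds
  wb[model$x_sds == 0] <- NA_real_
  tibble(wavelength = model$axis, beta = unname(model$beta),
         sd = unname(model$x_sds), weighted_beta = unname(wb))
}
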