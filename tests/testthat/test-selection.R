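test_that("wrc_select finds spikes, collapses plateaus, rejects monotone curves", {
  axis <- seq(550, 600, by = 1)
  p <- length(axis)

  wb <- rep(0.1, p); wb[c(11, 31)] <- c(2, 3)
  res <- wrc_select(wb, axis, rep(1, p), k_max = 5)
  expect_setequal(res$indices, c(11, 31))
  expect_equal(res$wavelengths_nm, axis[c(11, 31)])

  plateau <- rep(0, p); plateau[20:24] <- 1
  expect_equal(wrc_select(plateau, axis, rep(1, p), k_max = 1)$indices, 22)

  expect_error(wrc_select(seq_len(p), axis, rep(1, p)), "peaks")
  expect_error(wrc_select(rep(1, p), axis, rep(1, p)))

  # intensity weighting decides the ranking between equal-height peaks
  two <- rep(0, p); two[c(11, 31)] <- 1
  intensity <- rep(1, p); intensity[31] <- 3
  expect_equal(wrc_select(two, axis, intensity, k_max = 1)$indices, 31)

  # exhaustive interior scan oracle on a smooth random curve
  set.seed(13)
  smooth <- as.numeric(stats::filter(rnorm(p), rep(1 / 7, 7), circular = TRUE))
  intensity <- runif(p, 0.5, 1)
  got <- wrc_select(smooth, axis, intensity, k_max = 4)
  v <- abs(smooth)
  peaks <- integer(0)
  for (i in 2:(p - 1)) if (v[i] > v[i - 1] && v[i] > v[i + 1]) peaks <- c(peaks, i)
  want <- peaks[order(v[peaks] * intensity[peaks], decreasing = TRUE)][1:4]
  expect_setequal(got$indices, want)
})

test_that("sfs_select is greedy on cross-validated misclassification", {
  set.seed(14)
  y <- rep_len(0:2, 45)
  X <- matrix(rnorm(45 * 6), 45, 6)
  X[, 3] <- y
  df <- as_spectra(X, class = y)

  expect_equal(sfs_select(df, k = 1, seed = 1)$indices, 3L)

  res <- sfs_select(df, k = 3, folds = 5, seed = 2)
  expect_identical(res$trace, sfs_select(df, k = 3, folds = 5, seed = 2)$trace)

  # literal greedy loop with the same fold assignment
  fold_id <- eggspec:::with_seed(eggspec:::derive_seed(2, "sfs_folds"),
                                 sample(rep_len(1:5, 45)))
  selected <- integer(0)
  for (step in 1:3) {
    cand <- setdiff(1:6, selected)
    errs <- sapply(cand, function(j) {
      eggspec:::cv_misclass(X[, c(selected, j), drop = FALSE], y, fold_id)
    })
    selected <- c(selected, cand[which.min(errs)])
  }
  expect_equal(res$trace$index, selected)
})

test_that("sfs step one is exhaustively optimal among single columns", {
  df <- small_transmittance(seed = 6, lo = 560, hi = 575)
  X <- spectra_matrix(df)
  y <- df$class
  res <- sfs_select(df, k = 1, folds = 5, seed = 4)
  fold_id <- eggspec:::with_seed(eggspec:::derive_seed(4, "sfs_folds"),
                                 sample(rep_len(1:5, nrow(X))))
  errs <- sapply(seq_len(ncol(X)), function(j) {
    eggspec:::cv_misclass(X[, j, drop = FALSE], y, fold_id)
  })
  expect_equal(min(errs), res$trace$criterion[1])
  expect_equal(errs[res$indices], min(errs))
})

test_that("spa_select follows the projection recursion and avoids collinearity", {
  # orthogonal columns of distinct norms: picks follow descending residual norm
  set.seed(15)
  Q <- qr.Q(qr(matrix(rnorm(20 * 5), 20, 5)))
  X <- Q %*% diag(c(5, 4, 3, 2, 1))
  Xc <- scale(X, center = TRUE, scale = FALSE)
  chain <- eggspec:::spa_chain(Xc, start = 1, k = 4)
  # with near-orthogonal centered columns the largest remaining norms win
  norms <- sqrt(colSums(Xc^2))
  expect_equal(chain$indices[1], 1)
  rest <- setdiff(order(norms, decreasing = TRUE), 1)
  expect_equal(chain$indices[-1], rest[1:3])

  # a duplicated column is never selected twice
  Xd <- cbind(X, X[, 2])
  ch <- eggspec:::spa_chain(scale(Xd, center = TRUE, scale = FALSE), start = 2, k = 5)
  expect_false(anyDuplicated(ch$indices) > 0)
  expect_false(all(c(2, 6) %in% ch$indices))

  # full selector: chain from every start matches the literal QR oracle
  set.seed(16)
  Xr <- matrix(rnorm(15 * 30), 15, 30)
  Xrc <- scale(Xr, center = TRUE, scale = FALSE)
  for (s in c(1, 8, 17, 30)) {
    expect_equal(eggspec:::spa_chain(Xrc, s, 3)$indices, spa_oracle(Xrc, s, 3))
  }

  df <- as_spectra(Xr, class = rep_len(0:2, 15))
  res <- spa_select(df, k = 3, seed = 3)
  expect_equal(length(res$wavelengths_nm), 3)
  expect_identical(tidy(res), tidy(spa_select(df, k = 3, seed = 3)))

  # orthogonality: projected candidates are orthogonal to the selected span
  sel <- res$trace$index[1:2]
  vs <- Xrc[, sel[1]]
  V <- Xrc - vs %*% t(drop(crossprod(vs, Xrc)) / sum(vs^2))
  expect_lt(max(abs(crossprod(V, Xrc[, sel[1]]))) / sum(Xrc[, sel[1]]^2), 1e-10)
})

test_that("pool_bands forms the sorted de-duplicated union", {
  a <- fake_selection("wrc", c(556, 566, 578, 596))
  b <- fake_selection("sfs", c(577, 597, 598))
  c_ <- fake_selection("spa", c(577, 589, 598))
  pooled <- pool_bands(list(a, b, c_))
  expect_equal(pooled$method, "pooled")
  expect_equal(pooled$wavelengths_nm,
               c(556, 566, 577, 578, 589, 596, 597, 598))
  expect_equal(length(pooled$wavelengths_nm), 8)

  expect_equal(length(pool_bands(list(fake_selection("wrc", c(1, 2, 3)),
                                      fake_selection("sfs", c(4, 5, 6))))$wavelengths_nm), 6)
  expect_equal(length(pool_bands(list(a, a))$wavelengths_nm), 4)
  expect_error(pool_bands(list()))
})

test_that("stepwise_select gates entry by the partial-F p-value", {
  set.seed(17)
  n <- 60
  y <- rep_len(0:2, n)
  X <- matrix(rnorm(n * 5), n, 5)
  X[, 2] <- y + rnorm(n, sd = 0.3) # strong true effect
  df <- as_spectra(X, class = y)

  strict <- stepwise_select(df, 1e-4)
  expect_equal(strict$indices[1], 2L)

  loose <- stepwise_select(df, 0.999999)
  expect_equal(length(loose$indices), 5)

  # trace p-values match nested lm/anova at every step
  tr <- strict$trace
  for (s in unique(tr$step)) {
    rows <- tr[tr$step == s, ]
    base <- tr$index[tr$selected & tr$step < s]
    for (i in seq_len(nrow(rows))) {
      expect_equal(rows$p_value[i],
                   partial_f_oracle(X, y, base, rows$index[i]),
                   tolerance = 1e-10)
    }
  }

  # pass-through sentinel returns the input set unchanged
  pt <- stepwise_select(df, 0)
  expect_equal(pt$indices, 1:5)
  expect_equal(nrow(pt$trace), 0)
  expect_error(stepwise_select(df, 1.5))
})

test_that("stepwise thresholds yield nested band sets", {
  set.seed(18)
  for (rep in 1:10) {
    n <- 50
    y <- rep_len(0:2, n)
    X <- matrix(rnorm(n * 6), n, 6)
    X[, 2] <- y + rnorm(n, sd = 0.5)
    X[, 5] <- (y == 2) + rnorm(n, sd = 0.5)
    df <- as_spectra(X, class = y)
    prev <- integer(0)
    for (p_enter in c(1e-4, 1e-3, 1e-2, 5e-2)) {
      sel <- tryCatch(stepwise_select(df, p_enter)$indices, error = function(e) integer(0))
      expect_true(all(prev %in% sel))
      prev <- sel
    }
  }
})

test_that("select_bands extracts exact wavelength columns", {
  df <- random_spectra(n = 5, p = 10, seed = 19)
  sub <- select_bands(df, c(502, 505))
  expect_equal(spectra_axis(sub), c(502, 505))
  expect_equal(spectra_matrix(sub), spectra_matrix(df)[, c(3, 6)], ignore_attr = TRUE)
  expect_error(select_bands(df, 502.5), "not on the axis")
})
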