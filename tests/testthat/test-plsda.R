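test_that("the calibration/validation split is stratified and reproducible", {
  df <- random_spectra(n = 30, p = 5, seed = 1)
  sp <- split_calibration_validation(df, 0.7, seed = 9)
  expect_equal(nrow(sp$train), 3 * floor(0.7 * 10))
  expect_equal(as.vector(table(sp$train$class)), rep(7L, 3))
  expect_identical(sp, split_calibration_validation(df, 0.7, seed = 9))
  expect_false(identical(sp, split_calibration_validation(df, 0.7, seed = 10)))

  four <- random_spectra(n = 4, p = 3, seed = 2, classes = 0:1)
  half <- split_calibration_validation(four, 0.5, seed = 1)
  expect_equal(nrow(half$train), 2)
  expect_setequal(half$train$class, 0:1)
  expect_setequal(half$test$class, 0:1)

  expect_error(split_calibration_validation(df, 1.2))
  expect_error(split_calibration_validation(random_spectra(3, 3, classes = c(0, 0, 1))))
})

test_that("plsda_fit matches a literal NIPALS loop and the pseudoinverse limit", {
  set.seed(20)
  X <- matrix(rnorm(20 * 10), 20, 10)
  y <- rep_len(0:2, 20)
  df <- as_spectra(X, class = y)

  m <- plsda_fit(df, A = 3)
  oracle <- nipals_oracle(X, y, 3)
  for (a in 1:3) {
    sgn <- sign(sum(m$W[, a] * oracle$W[, a]))
    expect_equal(m$T[, a], sgn * oracle$T[, a], tolerance = 1e-8)
    expect_equal(m$P[, a], sgn * oracle$P[, a], tolerance = 1e-8)
  }
  expect_equal(m$beta, unname(oracle$beta), tolerance = 1e-8,
               ignore_attr = TRUE)

  full <- plsda_fit(df, A = 10)
  expect_equal(unname(full$beta), pinv_beta_oracle(X, y), tolerance = 1e-8)
})

test_that("the X and y decompositions reconstruct the training data", {
  df <- random_spectra(n = 25, p = 8, seed = 3)
  X <- spectra_matrix(df)
  Xc <- scale(X, center = TRUE, scale = FALSE)
  norms <- sapply(1:6, function(a) {
    m <- plsda_fit(df, A = a)
    expect_equal(Xc, m$T %*% t(m$P) + m$E, tolerance = 1e-10, ignore_attr = TRUE)
    expect_equal(df$class - mean(df$class),
                 drop(m$U %*% m$Q) + m$F, tolerance = 1e-10)
    norm(m$E, "F")
  })
  expect_true(all(diff(norms) < 1e-10))
})

test_that("a single informative column is recovered with one latent variable", {
  set.seed(7)
  X <- matrix(rnorm(150 * 6, sd = 0.3), 150, 6)
  y <- rep_len(0:2, 150)
  X[, 4] <- y
  m <- plsda_fit(as_spectra(X, class = y), A = 1)
  pred <- predict(m, as_spectra(X, class = y))
  expect_gte(cor(pred$.score, y), 0.99)
})

test_that("score thresholds assign nearest labels with boundaries going up", {
  expect_equal(eggspec:::score_to_class(c(0.4, 0.5, 1.2, 1.49, 1.5, 1.6, -3, 9)),
               c(0L, 1L, 1L, 1L, 2L, 2L, 0L, 2L))
})

test_that("a noiseless separable set is classified perfectly in training", {
  set.seed(8)
  y <- rep(0:2, each = 10)
  X <- cbind(y + 0.001 * rnorm(30), matrix(rnorm(30 * 4), 30, 4))
  df <- as_spectra(X, class = y)
  m <- plsda_fit(df, A = 2)
  expect_equal(predict(m, df)$.pred, y)
  expect_error(predict(m, random_spectra(5, 3)), "wavelengths")
})

test_that("choose_components prefers the simplest adequate model", {
  set.seed(9)
  y <- rep_len(0:2, 90)
  X <- cbind(y, matrix(rnorm(90 * 7, sd = 0.3), 90, 7))
  df <- as_spectra(X, class = y)
  expect_equal(choose_components(df, A_max = 6, seed = 1), 1L)

  noise <- as_spectra(matrix(rnorm(90 * 8), 90, 8), class = y)
  expect_equal(choose_components(noise, A_max = 6, seed = 1), 1L)
  expect_identical(choose_components(df, A_max = 6, seed = 3),
                   choose_components(df, A_max = 6, seed = 3))
})

test_that("classification reports match a counting oracle and handle edge cases", {
  expect_equal(classification_report(rep(0:1, c(35, 65)),
                                     rep(c(0, 1, 0, 1), c(30, 5, 5, 60)))$per_class$accuracy[1],
               90)

  perfect <- classification_report(rep(0:2, 4), rep(0:2, 4))
  expect_equal(perfect$total_accuracy, 100)
  expect_true(all(perfect$per_class$recall == 100))
  expect_true(all(perfect$per_class$precision == 100))

  set.seed(10)
  truth <- sample(0:2, 60, replace = TRUE)
  est <- sample(0:2, 60, replace = TRUE)
  rep_ <- classification_report(truth, est)
  oracle <- report_oracle(truth, est)
  for (cl in 0:2) {
    counts <- oracle[[as.character(cl)]]
    row <- rep_$per_class[rep_$per_class$class == cl, ]
    expect_equal(unlist(row[, c("tp", "tn", "fp", "fn")]), counts, ignore_attr = TRUE)
    expect_equal(row$accuracy, 100 * (counts["tp"] + counts["tn"]) / 60, ignore_attr = TRUE)
    expect_equal(row$recall, 100 * counts["tp"] / (counts["tp"] + counts["fn"]), ignore_attr = TRUE)
  }
  expect_equal(rep_$total_accuracy, 100 * sum(truth == est) / 60)
  expect_equal(sum(rep_$confusion), 60)
  expect_equal(100 * sum(diag(rep_$confusion)) / 60, rep_$total_accuracy)

  # never predicted class: precision undefined, reported missing
  r0 <- classification_report(c(0, 0, 1, 1), c(0, 0, 0, 0))
  expect_true(is.na(r0$per_class$precision[r0$per_class$class == 1]))
  expect_error(classification_report(integer(0), integer(0)))
})

test_that("weighted beta equals beta times training sd and matches an autoscaled refit", {
  df <- random_spectra(n = 40, p = 6, seed = 11)
  X <- spectra_matrix(df)

  unit <- as_spectra(scale(X), class = df$class) # sd 1 columns
  mu <- plsda_fit(unit, A = 3)
  wb <- weighted_beta(mu)
  expect_equal(unname(wb$weighted_beta), unname(wb$beta), tolerance = 1e-10)

  m <- plsda_fit(df, A = 6)
  X2 <- X; X2[, 2] <- 2 * X[, 2]
  m2 <- plsda_fit(as_spectra(X2, class = df$class), A = 6)
  expect_equal(unname(m2$beta[2]), unname(m$beta[2] / 2), tolerance = 1e-8)
  expect_equal(unname(weighted_beta(m2)$weighted_beta[2]),
               unname(weighted_beta(m)$weighted_beta[2]), tolerance = 1e-8)

  # the weighted vector is proportional to the coefficients of a refit on
  # autoscaled columns (same A); one positive constant relates them
  ms <- plsda_fit(as_spectra(scale(X), class = df$class), A = 6)
  ratio <- weighted_beta(m)$weighted_beta / ms$beta
  expect_true(all(abs(ratio - ratio[1]) < 1e-8 * abs(ratio[1])))
  expect_gt(ratio[1], 0)
})

test_that("tidy, glance and augment expose the fitted model", {
  df <- random_spectra(n = 30, p = 5, seed = 12)
  m <- plsda_fit(df, A = 2)
  td <- tidy(m)
  expect_equal(nrow(td), 5)
  expect_named(td, c("wavelength", "beta", "sd", "weighted_beta"))
  gl <- glance(m)
  expect_equal(gl$n_components, 2)
  expect_equal(gl$n, 30)
  au <- augment(m, df)
  expect_true(all(c(".score", ".pred") %in% names(au)))
  expect_equal(nrow(au), 30)
})
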