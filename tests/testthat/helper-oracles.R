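# Independent oracle implementations used to cross-check the package's
# numerics. Each is written as a plain literal loop so it shares no code path
# with the implementation it checks.

# Literal NIPALS PLS1 loop: center, iterate weight/score/loading/deflation.
nipals_oracle <- function(X, y, A) {
  Xc <- scale(X, center = TRUE, scale = FALSE)
  yc <- y - mean(y)
  n <- nrow(X); p <- ncol(X)
  W <- matrix(0, p, A); P <- matrix(0, p, A); Tm <- matrix(0, n, A)
  q <- numeric(A)
  for (a in 1:A) {
    w <- t(Xc) %*% yc
    w <- w / sqrt(sum(w^2))
    t_ <- Xc %*% w
    p_ <- t(Xc) %*% t_ / sum(t_^2)
    q_ <- sum(yc * t_) / sum(t_^2)
    Xc <- Xc - t_ %*% t(p_)
    yc <- yc - t_ * q_
    W[, a] <- w; P[, a] <- p_; Tm[, a] <- t_; q[a] <- q_
  }
  beta <- W %*% solve(t(P) %*% W) %*% q
  list(W = W, P = P, T = Tm, q = q, beta = drop(beta))
}

# Minimum-norm least-squares coefficients of centered y on centered X,
# via the SVD pseudoinverse.
pinv_beta_oracle <- function(X, y) {
  Xc <- scale(X, center = TRUE, scale = FALSE)
  yc <- y - mean(y)
  s <- svd(Xc)
  keep <- s$d > 1e-10 * s$d[1]
  drop(s$v[, keep, drop = FALSE] %*% ((t(s$u[, keep, drop = FALSE]) %*% yc) / s$d[keep]))
}

# Literal successive-projection recursion from one start column, computing
# the projection with an explicit QR-based projector each step.
spa_oracle <- function(Xc, start, k) {
  p <- ncol(Xc)
  selected <- start
  for (step in seq_len(k - 1)) {
    Q <- qr.Q(qr(Xc[, selected, drop = FALSE]))
    resid <- Xc - Q %*% (t(Q) %*% Xc)
    cand <- setdiff(seq_len(p), selected)
    norms <- apply(resid[, cand, drop = FALSE], 2, function(v) sqrt(sum(v^2)))
    selected <- c(selected, cand[which.max(norms)])
  }
  selected
}

# Windowed polynomial least-squares derivative at every point (including the
# truncated edge windows), via lm() on the local offsets.
sg_oracle <- function(x, axis, deriv, window, polyorder) {
  p <- length(x)
  hw <- (window - 1) %/% 2
  out <- numeric(p)
  for (i in seq_len(p)) {
    idx <- max(1, i - hw):min(p, i + hw)
    d <- axis[idx] - axis[i]
    fit <- lm(x[idx] ~ poly(d, degree = polyorder, raw = TRUE))
    out[i] <- factorial(deriv) * coef(fit)[deriv + 1]
  }
  out
}

# Partial-F p-value of adding column j to an OLS model on columns `base`,
# via nested lm() + anova().
partial_f_oracle <- function(X, y, base, j) {
  d0 <- if (length(base) == 0) {
    lm(y ~ 1)
  } else {
    lm(y ~ ., data = as.data.frame(X[, base, drop = FALSE]))
  }
  d1 <- lm(y ~ ., data = as.data.frame(X[, c(base, j), drop = FALSE]))
  anova(d0, d1)[2, "Pr(>F)"]
}

# Brute-force classification report by explicit counting loops.
report_oracle <- function(truth, estimate) {
  levels <- sort(unique(c(truth, estimate)))
  out <- list()
  for (cl in levels) {
    tp <- tn <- fp <- fn <- 0
    for (i in seq_along(truth)) {
      if (truth[i] == cl && estimate[i] == cl) tp <- tp + 1
      if (truth[i] == cl && estimate[i] != cl) fn <- fn + 1
      if (truth[i] != cl && estimate[i] == cl) fp <- fp + 1
      if (truth[i] != cl && estimate[i] != cl) tn <- tn + 1
    }
    out[[as.character(cl)]] <- c(tp = tp, tn = tn, fp = fp, fn = fn)
  }
  out
}
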