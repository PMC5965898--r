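# Single-variance-component linear mixed model engine.
#
# Model: y = W alpha + g beta + u + e, with u ~ N(0, sigma_g^2 K) and
# e ~ N(0, sigma_e^2 I). Writing lambda = sigma_g^2 / sigma_e^2 and
# eigendecomposing K = U D U', rotation by U' diagonalizes the covariance:
# Var(U'y) = sigma_e^2 (lambda D + I). The profile log-likelihood in lambda is
# maximized by 1-D search on the log scale; per-SNP fixed effects are then
# tested by Wald tests under generalized least squares at the null-model
# lambda, with the residual variance re-estimated per SNP. With K = I the
# weights are constant and every statistic coincides exactly with OLS.

# Null-model fit: rotate by eigenvectors of K and profile the likelihood.
fit_lmm_null <- function(y, W, K, reml = FALSE) {
  n <- length(y)
  eg <- eigen(K, symmetric = TRUE)
  d <- pmax(eg$values, 0)
  U <- eg$vectors
  yt <- crossprod(U, y)
  Wt <- crossprod(U, W)
  p <- ncol(W)
  nll <- function(log_lambda) {
    lambda <- exp(log_lambda)
    v <- lambda * d + 1
    w <- 1 / v
    sw <- sqrt(w)
    Ws <- Wt * sw
    ys <- yt * sw
    qr_w <- qr(Ws)
    rss <- sum(qr.resid(qr_w, ys)^2)
    if (reml) {
      df <- n - p
      0.5 * (df * log(rss / df) + sum(log(v)) +
               2 * sum(log(abs(diag(qr.R(qr_w))))))
    } else {
      0.5 * (n * log(rss / n) + sum(log(v)))
    }
  }
  opt <- stats::optimize(nll, interval = c(-12, 12))
  lambda <- exp(opt$minimum)
  v <- lambda * d + 1
  w <- 1 / v
  sw <- sqrt(w)
  Ws <- Wt * sw
  ys <- yt * sw
  qr_w <- qr(Ws)
  rss <- sum(qr.resid(qr_w, ys)^2)
  list(lambda = lambda, sigma2_e = rss / (n - p),
       U = U, d = d, weights = w, yt = yt, Wt = Wt, reml = reml)
}

# Vectorized Wald scan: regress rotated, weighted phenotype on each rotated,
# weighted SNP after projecting out the covariates (Frisch-Waugh-Lovell).
lmm_wald_scan <- function(null_fit, G_rotated) {
  sw <- sqrt(null_fit$weights)
  ys <- null_fit$yt * sw
  Ws <- null_fit$Wt * sw
  Gs <- G_rotated * sw
  qr_w <- qr(Ws)
  y_r <- qr.resid(qr_w, ys)
  G_r <- qr.resid(qr_w, Gs)
  gg <- colSums(G_r^2)
  gy <- as.vector(crossprod(G_r, y_r))
  n <- length(ys)
  df <- n - ncol(Ws) - 1
  beta <- gy / gg
  rss <- sum(y_r^2) - beta * gy
  sigma2 <- rss / df
  se <- sqrt(sigma2 / gg)
  tstat <- beta / se
  p <- 2 * stats::pt(-abs(tstat), df)
  list(beta = beta, se = se, p = p, df = df, gg = gg)
}
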