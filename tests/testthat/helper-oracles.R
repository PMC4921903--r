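# Independent oracles used to cross-check the package implementations.
# These are deliberately coded from first principles (textbook sum formulas,
# dense linear algebra) and share no code with the functions they check.

# Pearson correlation from the raw sum formula
pearson_oracle <- function(x, y) {
  n <- length(x)
  num <- n * sum(x * y) - sum(x) * sum(y)
  den <- sqrt(n * sum(x^2) - sum(x)^2) * sqrt(n * sum(y^2) - sum(y)^2)
  num / den
}

profile_difference_oracle <- function(a, b) 1 - abs(pearson_oracle(a, b))

magnitude_difference_oracle <- function(a, b)
  abs(sqrt(sum(a * a)) - sqrt(sum(b * b)))

# Construct paired posterior-draw sets whose per-draw Pearson correlations
# take prescribed values exactly: fixed profile u against
# rho*u + sqrt(1-rho^2)*v with u, v zero-mean, orthogonal, equal norm.
make_corr_draws <- function(rhos, tt = c(0, 2.5, 5, 10, 20, 40, 80)) {
  T <- length(tt)
  u <- seq_len(T) - mean(seq_len(T))
  w <- rep_len(c(1, -1), T)
  v <- w - sum(w * u) / sum(u * u) * u
  v <- v - mean(v)
  v <- v * sqrt(sum(u^2) / sum(v^2))   # zero-mean, orthogonal, equal norm
  n <- length(rhos)
  A <- array(rep(u, each = n), c(n, 1, T))
  B <- array(0, c(n, 1, T))
  for (i in seq_len(n))
    B[i, 1, ] <- rhos[i] * u + sqrt(1 - rhos[i]^2) * v
  list(A = tfa_posterior(A, "tf1", tt),
       B = tfa_posterior(B, "tf1", tt),
       u = u, v = v)
}

# Closed-form Gaussian posterior for the activities when the weights, the
# noise sd and the baselines are all fixed: dense precision-matrix algebra
# over vec(c) with index k = (m-1)*T + t.
conjugate_posterior <- function(Y, A, tt, sigma, tau_c, c0_sd) {
  T <- length(tt); M <- ncol(A)
  Q1 <- matrix(0, T, T)
  Q1[1, 1] <- 1 / c0_sd^2
  for (t in 2:T) {
    q <- 1 / (tau_c^2 * (tt[t] - tt[t - 1]))
    Q1[t, t] <- Q1[t, t] + q
    Q1[t - 1, t - 1] <- Q1[t - 1, t - 1] + q
    Q1[t, t - 1] <- Q1[t, t - 1] - q
    Q1[t - 1, t] <- Q1[t - 1, t] - q
  }
  P <- matrix(0, M * T, M * T); h <- numeric(M * T)
  for (m in seq_len(M)) {
    idx <- (m - 1) * T + seq_len(T)
    P[idx, idx] <- P[idx, idx] + Q1
  }
  for (t in seq_len(T)) {
    idx <- (seq_len(M) - 1) * T + t
    P[idx, idx] <- P[idx, idx] + crossprod(A) / sigma^2
    h[idx] <- crossprod(A, Y[, t]) / sigma^2
  }
  Sig <- solve(P)
  mu <- as.vector(Sig %*% h)
  list(mean = matrix(mu, M, T, byrow = TRUE),
       var = matrix(diag(Sig), M, T, byrow = TRUE))
}

# batch-means Monte-Carlo standard errors
mcse_mean <- function(x, n_batches = 40) {
  b <- floor(length(x) / n_batches)
  bm <- colMeans(matrix(x[seq_len(b * n_batches)], nrow = b))
  sd(bm) / sqrt(n_batches)
}
mcse_var <- function(x, n_batches = 40) {
  mcse_mean((x - mean(x))^2, n_batches)
}

# small expression table on disk for I/O tests
write_expr_fixture <- function(lines, path = tempfile(fileext = ".tsv")) {
  writeLines(lines, path)
  path
}
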