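# Independent brute-force oracles. These deliberately use scalar loops and
# explicit index walking, never the package's vectorized code paths, so the
# two implementations can check each other.

# reference coefficient sets (stimulated / immobilized class means and SDs
# of the one-lag model, and their per-parameter spreads)
okt3_beta <- c(0.6443, 0.6674, -0.3438)
okt3_sd <- c(0.0314, 0.0316, 0.0541)
pll_beta <- c(0.5671, 0.5943, -0.1992)
pll_sd <- c(0.0612, 0.0613, 0.1043)

# enumerate the valid region and lagged columns pixel by pixel
oracle_design <- function(px, L = 1L) {
  m <- nrow(px); n <- ncol(px)
  offsets <- list()
  for (di in 0:L) for (dj in 0:L) {
    if (di == 0L && dj == 0L) next
    offsets[[length(offsets) + 1L]] <- c(di, dj)
  }
  # match package ordering: row offset major
  ord <- order(vapply(offsets, `[`, 0, 1), vapply(offsets, `[`, 0, 2))
  offsets <- offsets[ord]
  y <- c(); X <- NULL
  rows <- list()
  for (j in (L + 1L):n) {       # column-major walk over the valid region
    for (i in (L + 1L):m) {
      y <- c(y, px[i, j])
      xr <- vapply(offsets, function(o) px[i - o[1], j - o[2]], 0)
      rows[[length(rows) + 1L]] <- xr
    }
  }
  X <- do.call(rbind, rows)
  list(y = y, X = X, offsets = offsets)
}

# normal equations and HC0 sandwich assembled term by term
oracle_ols <- function(px, L = 1L) {
  d <- oracle_design(px, L)
  y <- d$y; X <- d$X
  N <- length(y); k <- ncol(X)
  XtX <- matrix(0, k, k); Xty <- numeric(k)
  for (r in seq_len(N)) {
    for (a in seq_len(k)) {
      Xty[a] <- Xty[a] + X[r, a] * y[r]
      for (b in seq_len(k)) XtX[a, b] <- XtX[a, b] + X[r, a] * X[r, b]
    }
  }
  beta <- solve(XtX, Xty)
  e <- numeric(N)
  for (r in seq_len(N)) e[r] <- y[r] - sum(X[r, ] * beta)
  meat <- matrix(0, k, k)
  for (r in seq_len(N)) {
    for (a in seq_len(k)) for (b in seq_len(k)) {
      meat[a, b] <- meat[a, b] + e[r]^2 * X[r, a] * X[r, b]
    }
  }
  XtX_inv <- solve(XtX)
  V <- XtX_inv %*% meat %*% XtX_inv
  list(beta = beta, white_cov = V, t_stats = beta / sqrt(diag(V)),
       residuals = e, r2_uncentered = 1 - sum(e^2) / sum(y^2))
}

# scalar-loop forward recursion given explicit boundary and innovations
oracle_recursion <- function(first_row, first_col, beta, e) {
  n <- length(first_row); m <- length(first_col)
  v <- matrix(0, m, n)
  v[1, ] <- first_row
  v[, 1] <- first_col
  for (i in 2:m) for (j in 2:n) {
    v[i, j] <- beta[1] * v[i, j - 1] + beta[2] * v[i - 1, j] +
      beta[3] * v[i - 1, j - 1] + e[i - 1, j - 1]
  }
  v
}

# a deterministic zero-noise recursion image for exactness checks
zero_noise_image <- function(m = 40, n = 40, beta = c(0.6, 0.3, 0.05),
                             seed = 42) {
  spec <- lag_sim_spec(shape = c(m, n), beta = beta, innovation_sd = 0,
                       boundary_mean = 100, boundary_sd = 10, seed = seed)
  simulate_lag_image(spec)
}

# Gaussian parameter clouds around the two reference coefficient sets
gaussian_cloud <- function(n, center, sd) {
  matrix(stats::rnorm(n * length(center), mean = rep(center, each = n),
                      sd = rep(sd, each = n)), nrow = n)
}
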