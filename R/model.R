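# Spatial-lag (digital PDE) image model.
#
# An image v is modelled pixel-wise as a linear combination of copies of
# itself shifted by small integer offsets (spatial lags):
#
#   v[i, j] = sum_h beta_h * v[i - di_h, j - dj_h] + e[i, j]
#
# with quadrant-causal offsets (di, dj), 0 <= di, dj <= L, (0,0) excluded.
# For one lag (L = 1) the regressors are the left, upper and upper-left
# neighbours, with coefficients (beta_01, beta_10, beta_11). The model is
# estimated by OLS on the fully interior region, with a White (HC0)
# heteroskedasticity-robust parameter covariance for the t tests.

#' Spatial lag structure
#'
#' Enumerates the lag offsets for a given order `L`: all integer pairs
#' `(di, dj)` with `0 <= di, dj <= L` except `(0, 0)`, ordered row-offset
#' major so that `L = 1` gives exactly (0,1), (1,0), (1,1). The number of
#' offsets is `(L + 1)^2 - 1`.
#'
#' @param order positive integer lag order `L`.
#' @return An object of class `lag_structure`: list with `order`, `offsets`
#'   (k x 2 integer matrix, columns `di`, `dj`) and `k`.
#' @examples
#' lag_structure(1)$offsets
#' @export
lag_structure <- function(order) {
  order <- as.integer(order)
  if (length(order) != 1L || is.na(order) || order < 1L) {
    stop("`order` must be a positive integer", call. = FALSE)
  }
  grid <- expand.grid(dj = 0:order, di = 0:order)[, c("di", "dj")]
  grid <- grid[order(grid$di, grid$dj), ]
  grid <- grid[!(grid$di == 0L & grid$dj == 0L), , drop = FALSE]
  offsets <- as.matrix(grid)
  dimnames(offsets) <- list(NULL, c("di", "dj"))
  structure(
    list(order = order, offsets = offsets, k = nrow(offsets)),
    class = "lag_structure"
  )
}

lag_labels <- function(lags) {
  sprintf("b%d%d", lags$offsets[, "di"], lags$offsets[, "dj"])
}

#' Build the lagged regression dataset for an image
#'
#' Restricts the image to its fully interior valid region
#' (rows `L..m-1`, columns `L..n-1`, 0-based), flattens it in column-major
#' order as the response, and builds one design column per lag offset by
#' shifting the image. No padding or wraparound: an `m x n` image at
#' `L = 1` yields `N = (m-1)(n-1)` samples.
#'
#' @param img a [grayscale_image] or numeric matrix.
#' @param lags a [lag_structure] (or integer order, converted).
#' @return A list of class `regression_dataset`: `response` (length N),
#'   `design` (N x k matrix, columns named after the offsets),
#'   `lags`, `shape` (c(m, n)) and `n_samples`.
#' @export
build_lagged_design <- function(img, lags = lag_structure(1)) {
  img <- as_grayscale_image(img)
  if (!inherits(lags, "lag_structure")) lags <- lag_structure(lags)
  px <- img$pixels
  m <- nrow(px); n <- ncol(px)
  L <- lags$order
  if (m <= L || n <= L) {
    stop(sprintf(
      "empty design: lag order %d needs an image larger than %d x %d (got %d x %d)",
      L, L, L, m, n), call. = FALSE)
  }
  rows <- (L + 1L):m  # 1-based; valid region i >= L (0-based)
  cols <- (L + 1L):n
  response <- as.vector(px[rows, cols])
  k <- lags$k
  design <- matrix(0, nrow = length(response), ncol = k)
  for (h in seq_len(k)) {
    di <- lags$offsets[h, "di"]; dj <- lags$offsets[h, "dj"]
    design[, h] <- as.vector(px[rows - di, cols - dj])
  }
  colnames(design) <- lag_labels(lags)
  structure(
    list(response = response, design = design, lags = lags,
         shape = c(m, n), n_samples = length(response)),
    class = "regression_dataset"
  )
}

#' Fit the spatial-lag model by OLS with White robust covariance
#'
#' Minimizes the residual sum of squares of the no-intercept regression of
#' the interior pixels on their lagged copies. Parameter covariance is the
#' HC0 sandwich \eqn{(X'X)^{-1} X' diag(e^2) X (X'X)^{-1}}; t statistics use
#' its diagonal with N - k degrees of freedom. A joint Wald chi-square
#' statistic \eqn{\beta' V^{-1} \beta} (df = k) is reported alongside.
#'
#' @param data a `regression_dataset` from [build_lagged_design].
#' @param r_squared which goodness-of-fit to report as `r_squared`:
#'   `"uncentered"` (default, `1 - sum(e^2)/sum(y^2)`, the natural choice
#'   for a through-the-origin model) or `"centered"` (squared correlation
#'   of fitted and observed). Both are always stored.
#' @return An object of class `image_model_fit`: `beta`, `se`, `t_stats`,
#'   `p_values`, `white_cov`, `residuals`, `fitted`, `r_squared`,
#'   `r_squared_uncentered`, `r_squared_centered`, `wald_stat`, `wald_p`,
#'   `lag_order`, `offsets`, `n_samples`, `shape`.
#' @export
fit_ols <- function(data, r_squared = c("uncentered", "centered")) {
  r_squared <- match.arg(r_squared)
  if (!inherits(data, "regression_dataset")) {
    stop("`data` must come from build_lagged_design()", call. = FALSE)
  }
  X <- data$design
  y <- data$response
  N <- length(y)
  k <- ncol(X)
  if (N <= k) {
    stop(sprintf("insufficient samples: N = %d <= k = %d", N, k),
         call. = FALSE)
  }
  sv <- svd(X, nu = 0)
  if (sv$d[k] <= 1e-10 * sv$d[1]) {
    # name the columns loading on the (near-)null space
    null_dirs <- sv$v[, sv$d <= 1e-10 * sv$d[1], drop = FALSE]
    loading <- sqrt(rowSums(null_dirs^2))
    bad <- colnames(X)[loading > 1 / sqrt(k) / 2]
    stop("collinear design (rank deficient); offending columns: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  XtX <- crossprod(X)
  XtX_inv <- chol2inv(chol(XtX))
  beta <- drop(XtX_inv %*% crossprod(X, y))
  names(beta) <- colnames(X)
  fitted <- drop(X %*% beta)
  e <- y - fitted
  meat <- crossprod(X * e)           # X' diag(e^2) X
  V <- XtX_inv %*% meat %*% XtX_inv
  V <- (V + t(V)) / 2
  dimnames(V) <- list(names(beta), names(beta))
  se <- sqrt(diag(V))
  t_stats <- beta / se
  p_values <- 2 * stats::pt(-abs(t_stats), df = N - k)
  r2_unc <- 1 - sum(e^2) / sum(y^2)
  r2_cen <- if (stats::sd(fitted) > 0 && stats::sd(y) > 0) {
    stats::cor(fitted, y)^2
  } else NA_real_
  wald <- drop(crossprod(beta, solve(V, beta)))
  structure(
    list(
      beta = beta, se = se, t_stats = t_stats, p_values = p_values,
      white_cov = V, residuals = e, fitted = fitted,
      r_squared = if (r_squared == "uncentered") r2_unc else r2_cen,
      r_squared_uncentered = r2_unc, r_squared_centered = r2_cen,
      wald_stat = wald, wald_p = stats::pchisq(wald, df = k, lower.tail = FALSE),
      lag_order = data$lags$order, offsets = data$lags$offsets,
      n_samples = N, shape = data$shape,
      significant = NA  # set by select_lag_order
    ),
    class = "image_model_fit"
  )
}

#' @export
print.image_model_fit <- function(x, ...) {
  cat(sprintf("<image_model_fit> lag order %d, N = %d, R^2 = %.4f\n",
              x$lag_order, x$n_samples, x$r_squared))
  tab <- data.frame(beta = x$beta, se = x$se, t = x$t_stats, p = x$p_values)
  print(format(tab, digits = 4))
  if (!is.na(x$significant)) {
    cat(sprintf("all parameters significant: %s\n", x$significant))
  }
  invisible(x)
}

#' Select the lag order by forward significance search
#'
#' Fits the one-lag model first. While every parameter is individually
#' significant (two-sided t test, `p < alpha_t`) and the order is below
#' `max_order`, the next order is tried; as soon as the larger model has
#' any insignificant parameter, the last fully significant model is
#' returned. If even the one-lag model has insignificant parameters it is
#' returned flagged `significant = FALSE` rather than raising an error.
#' The joint Wald chi-square test is flagged (`wald_significant`) at
#' `alpha_chi` but never drives selection.
#'
#' @param img a [grayscale_image] or numeric matrix.
#' @param alpha_t per-parameter t-test significance level.
#' @param alpha_chi joint Wald chi-square significance level.
#' @param max_order largest lag order tried.
#' @param ... passed to [fit_ols] (e.g. `r_squared`).
#' @return An `image_model_fit` with `significant` and `wald_significant`
#'   set.
#' @export
select_lag_order <- function(img, alpha_t = 0.05, alpha_chi = 0.01,
                             max_order = 3, ...) {
  img <- as_grayscale_image(img)
  if (max_order < 1) stop("`max_order` must be >= 1", call. = FALSE)
  fit <- fit_ols(build_lagged_design(img, lag_structure(1)), ...)
  fit$significant <- all(fit$p_values < alpha_t)
  if (!fit$significant) {
    fit$wald_significant <- fit$wald_p < alpha_chi
    return(fit)
  }
  L <- 1L
  while (L < max_order) {
    Lnext <- L + 1L
    d <- dim(img$pixels)
    if (d[1] <= Lnext || d[2] <= Lnext) break
    cand <- fit_ols(build_lagged_design(img, lag_structure(Lnext)), ...)
    cand$significant <- all(cand$p_values < alpha_t)
    if (!cand$significant) break
    fit <- cand
    L <- Lnext
  }
  fit$wald_significant <- fit$wald_p < alpha_chi
  fit
}

#' Reconstruct the model image from a fit
#'
#' Applies the estimated lag coefficients to the source image, giving the
#' fitted interior: an `(m - L) x (n - L)` image whose pixels plus the
#' residuals reproduce the observed valid region exactly. A 280 x 280
#' input at one lag yields a 279 x 279 model image.
#'
#' @param img the image the fit was produced from.
#' @param fit the corresponding `image_model_fit`.
#' @return A [grayscale_image] of shape `(m - L) x (n - L)`.
#' @export
reconstruct_model_image <- function(img, fit) {
  img <- as_grayscale_image(img)
  if (!inherits(fit, "image_model_fit")) {
    stop("`fit` must be an image_model_fit", call. = FALSE)
  }
  d <- dim(img$pixels)
  if (!identical(d, as.integer(fit$shape)) &&
      !isTRUE(all.equal(d, fit$shape))) {
    stop(sprintf("shape mismatch: fit was produced from a %d x %d image, got %d x %d",
                 fit$shape[1], fit$shape[2], d[1], d[2]), call. = FALSE)
  }
  data <- build_lagged_design(img, lag_structure(fit$lag_order))
  fitted <- drop(data$design %*% fit$beta)
  L <- fit$lag_order
  grayscale_image(matrix(fitted, nrow = d[1] - L, ncol = d[2] - L),
                  pixel_size_nm = img$pixel_size_nm)
}
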