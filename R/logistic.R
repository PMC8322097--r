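# Class-membership probabilities by binary logistic regression on the
# scalar FLD projection (intercept + slope), fitted by IRLS. Implemented
# directly rather than via glm() so that the convergence criteria and the
# separation diagnostics are exactly as documented.

#' Fit a binary logistic regression on projections
#'
#' Maximum-likelihood fit of `P(label = 1 | x) = plogis(intercept +
#' slope * x)` by iteratively reweighted least squares. Convergence is
#' declared when the maximum absolute score component falls below `1e-8`
#' or the relative log-likelihood change falls below `1e-10`; at most 100
#' iterations. Complete or quasi-complete separation (|slope| growing past
#' 1e3 with monotonically increasing likelihood) is detected and flagged
#' rather than treated as convergence; predicted probabilities are then
#' clamped to `[1e-12, 1 - 1e-12]`.
#'
#' @param projections numeric covariate vector (the FLD projections).
#' @param labels 0/1 vector (or logical, or a two-level factor whose second
#'   level is class 1). Both classes must be present.
#' @return An object of class `logistic_model`: `intercept`, `slope`,
#'   `converged`, `separated`, `n_iter`, `log_likelihood`, `n`.
#' @export
logistic_fit <- function(projections, labels) {
  x <- as.numeric(projections)
  if (is.factor(labels)) labels <- as.integer(labels) - 1L
  y <- as.numeric(labels)
  if (length(x) != length(y)) stop("`projections` and `labels` lengths differ",
                                   call. = FALSE)
  if (!all(y %in% c(0, 1))) stop("`labels` must be binary 0/1", call. = FALSE)
  if (length(unique(y)) < 2L) {
    stop("both classes must be present in `labels`", call. = FALSE)
  }
  if (!all(is.finite(x))) stop("non-finite projections", call. = FALSE)

  X <- cbind(1, x)
  dimnames(X) <- NULL
  # with complete (or boundary-tied quasi-complete) separation the MLE is
  # not finite regardless of what the iteration reports
  geom_sep <- max(x[y == 0]) <= min(x[y == 1]) ||
    min(x[y == 0]) >= max(x[y == 1])
  b <- c(0, 0)
  log1pexp <- function(z) ifelse(z > 30, z, log1p(exp(pmin(z, 30))))
  loglik <- function(b) {
    eta <- drop(X %*% b)
    sum(y * eta - log1pexp(eta))
  }
  ll_old <- loglik(b)
  ll_increasing <- TRUE
  converged <- FALSE
  separated <- FALSE
  it <- 0L
  while (it < 100L) {
    it <- it + 1L
    eta <- drop(X %*% b)
    p <- stats::plogis(eta)
    score <- drop(crossprod(X, y - p))
    if (max(abs(score)) < 1e-8) { converged <- TRUE; break }
    w <- pmax(p * (1 - p), 1e-12)
    H <- crossprod(X * sqrt(w))
    step <- tryCatch(solve(H, score), error = function(e) NULL)
    if (is.null(step)) { separated <- TRUE; break }
    b <- b + step
    ll_new <- loglik(b)
    if (ll_new < ll_old - 1e-12) ll_increasing <- FALSE
    if (abs(b[2]) > 1e3 && ll_increasing) { separated <- TRUE; break }
    if (is.finite(ll_old) && abs(ll_new - ll_old) <
        1e-10 * (abs(ll_old) + 1e-10)) {
      ll_old <- ll_new; converged <- TRUE; break
    }
    ll_old <- ll_new
  }
  if (geom_sep) { separated <- TRUE; converged <- FALSE }
  structure(
    list(intercept = unname(b[1]), slope = unname(b[2]), converged = converged,
         separated = separated, n_iter = it, log_likelihood = ll_old,
         n = length(y)),
    class = "logistic_model"
  )
}

#' @export
print.logistic_model <- function(x, ...) {
  cat(sprintf("<logistic_model> P(1|x) = plogis(%.4f + %.4f x)\n",
              x$intercept, x$slope))
  cat(sprintf("converged: %s, separated: %s, %d iterations, logLik %.4f\n",
              x$converged, x$separated, x$n_iter, x$log_likelihood))
  invisible(x)
}

#' Predict class-membership probabilities
#'
#' @param model a `logistic_model`.
#' @param projection numeric vector of projections.
#' @return Probabilities in `[0, 1]`, strictly monotone in the projection
#'   with the direction given by the sign of the slope. For a separated
#'   fit the values are clamped to `[1e-12, 1 - 1e-12]`.
#' @export
logistic_predict <- function(model, projection) {
  p <- stats::plogis(model$intercept + model$slope * as.numeric(projection))
  if (isTRUE(model$separated)) p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
  p
}
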