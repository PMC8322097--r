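# Two-class Fisher linear discriminant on per-image model parameters.
#
# Each image contributes one k-vector of lag coefficients; a class is a
# matrix with one such row per image. The discriminant direction maximizes
# between-class over within-class scatter and reduces, for two classes, to
# v ~ Sw^{-1} (m_B - m_A).

#' Class parameter matrix
#'
#' One row of lag-model coefficients per image of a single class.
#'
#' @param rows numeric matrix (images x parameters) or data frame.
#' @param label class name, e.g. `"PLL"` or `"OKT3"`.
#' @param image_ids optional character vector of per-row provenance;
#'   defaults to rownames or `img_1, img_2, ...`.
#' @return A `class_parameter_matrix`: list with `rows`, `label`,
#'   `image_ids`.
#' @export
class_parameter_matrix <- function(rows, label, image_ids = NULL) {
  if (is.data.frame(rows)) rows <- as.matrix(rows)
  if (!is.matrix(rows) || !is.numeric(rows)) {
    stop("`rows` must be a numeric matrix", call. = FALSE)
  }
  if (!all(is.finite(rows))) stop("non-finite parameter values", call. = FALSE)
  if (is.null(image_ids)) {
    image_ids <- rownames(rows)
    if (is.null(image_ids)) image_ids <- sprintf("img_%d", seq_len(nrow(rows)))
  }
  stopifnot(length(image_ids) == nrow(rows))
  structure(list(rows = rows, label = as.character(label),
                 image_ids = as.character(image_ids)),
            class = "class_parameter_matrix")
}

as_param_matrix <- function(x, label = "class") {
  if (inherits(x, "class_parameter_matrix")) return(x)
  class_parameter_matrix(x, label)
}

#' Fit a two-class Fisher linear discriminant
#'
#' Computes class means and the pooled within-class scatter
#' \eqn{S_w = \sum_c \sum_r (x - m_c)(x - m_c)'} and takes the projection
#' direction \eqn{v_c \propto S_w^{-1}(m_B - m_A)}, stored unit-norm and
#' oriented so class B projects higher. The decision threshold is the
#' midpoint of the two training projection means. If `S_w` is numerically
#' singular a ridge `1e-8 * trace(S_w)/k * I` is added with a warning.
#'
#' @param train_A,train_B training [class_parameter_matrix] objects (or
#'   bare matrices) for the two classes; each needs at least 2 rows.
#' @return An object of class `fld_model`: `v_c`, `class_labels`,
#'   `proj_mean_A/B`, `proj_sd_A/B`, `threshold`, `training_accuracy`,
#'   `orientation = "B-high"`.
#' @export
fld_fit <- function(train_A, train_B) {
  A <- as_param_matrix(train_A, "A")
  B <- as_param_matrix(train_B, "B")
  XA <- A$rows; XB <- B$rows
  if (nrow(XA) < 2L || nrow(XB) < 2L) {
    stop("each class needs at least 2 training rows", call. = FALSE)
  }
  if (ncol(XA) != ncol(XB)) stop("classes have different parameter counts",
                                 call. = FALSE)
  k <- ncol(XA)
  mA <- colMeans(XA); mB <- colMeans(XB)
  if (isTRUE(all.equal(mA, mB, tolerance = 1e-12))) {
    stop("degenerate classes: identical class means give zero between-class scatter",
         call. = FALSE)
  }
  Sw <- crossprod(sweep(XA, 2L, mA)) + crossprod(sweep(XB, 2L, mB))
  v <- tryCatch(solve(Sw, mB - mA), error = function(e) NULL)
  if (is.null(v) || rcond(Sw) < 1e-12) {
    warning("singular within-class scatter; using ridge regularization")
    Sw_r <- Sw + diag(1e-8 * sum(diag(Sw)) / k, k)
    v <- solve(Sw_r, mB - mA)
  }
  v <- v / sqrt(sum(v^2))
  pA <- drop(XA %*% v); pB <- drop(XB %*% v)
  if (mean(pB) < mean(pA)) { v <- -v; pA <- -pA; pB <- -pB }
  model <- structure(
    list(
      v_c = v,
      class_labels = c(A = A$label, B = B$label),
      proj_mean_A = mean(pA), proj_mean_B = mean(pB),
      proj_sd_A = stats::sd(pA), proj_sd_B = stats::sd(pB),
      threshold = (mean(pA) + mean(pB)) / 2,
      orientation = "B-high",
      training_accuracy = NA_real_
    ),
    class = "fld_model"
  )
  truth <- c(rep(A$label, length(pA)), rep(B$label, length(pB)))
  model$training_accuracy <-
    fld_classify(model, c(pA, pB), true_labels = truth)$accuracy
  model
}

#' @export
print.fld_model <- function(x, ...) {
  cat(sprintf("<fld_model> %s vs %s\n", x$class_labels["A"], x$class_labels["B"]))
  cat("v_c: ", paste(sprintf("%.4f", x$v_c), collapse = " "), "\n")
  cat(sprintf("projection means %.4f / %.4f, threshold %.4f\n",
              x$proj_mean_A, x$proj_mean_B, x$threshold))
  cat(sprintf("training accuracy %.3f\n", x$training_accuracy))
  invisible(x)
}

#' Project parameter rows onto the discriminant direction
#'
#' @param model an `fld_model`.
#' @param params a [class_parameter_matrix] or numeric matrix with the
#'   same parameter count as the training data.
#' @return Numeric vector of scalar projections `v_c . row`.
#' @export
fld_project <- function(model, params) {
  X <- if (inherits(params, "class_parameter_matrix")) params$rows else {
    if (is.null(dim(params))) matrix(params, nrow = 1) else as.matrix(params)
  }
  if (ncol(X) != length(model$v_c)) {
    stop(sprintf("dimension mismatch: model has %d parameters, data has %d",
                 length(model$v_c), ncol(X)), call. = FALSE)
  }
  unname(drop(X %*% model$v_c))
}

#' Classify projections
#'
#' Under the default midpoint rule a projection is assigned to class B iff
#' it is `>= threshold` (ties go to B deterministically). The optional
#' Gaussian rule compares the class likelihoods under normals fitted to
#' the training projections (equal priors).
#'
#' @param model an `fld_model`.
#' @param projections numeric vector of projections from [fld_project].
#' @param true_labels optional character vector of true class labels
#'   (values among the model's class labels) for scoring.
#' @param rule `"midpoint"` (default) or `"gaussian"`.
#' @return List with `labels`, and when `true_labels` is given `confusion`
#'   (2 x 2 table, truth in rows), `per_class_hits` and `accuracy`.
#' @export
fld_classify <- function(model, projections, true_labels = NULL,
                         rule = c("midpoint", "gaussian")) {
  rule <- match.arg(rule)
  lab_A <- model$class_labels[["A"]]; lab_B <- model$class_labels[["B"]]
  is_B <- if (rule == "midpoint") {
    projections >= model$threshold
  } else {
    dB <- stats::dnorm(projections, model$proj_mean_B, model$proj_sd_B)
    dA <- stats::dnorm(projections, model$proj_mean_A, model$proj_sd_A)
    dB >= dA
  }
  labels <- ifelse(is_B, lab_B, lab_A)
  out <- list(labels = labels, rule = rule)
  if (!is.null(true_labels)) {
    if (length(true_labels) != length(projections)) {
      stop("`true_labels` length mismatch", call. = FALSE)
    }
    lv <- c(lab_A, lab_B)
    confusion <- table(truth = factor(true_labels, levels = lv),
                       predicted = factor(labels, levels = lv))
    hits <- diag(confusion)
    out$confusion <- confusion
    out$per_class_hits <- stats::setNames(as.integer(hits), lv)
    out$accuracy <- sum(hits) / length(projections)
  }
  out
}

#' Serialize an FLD model to JSON
#'
#' @param model an `fld_model`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
fld_save_json <- function(model, path) {
  obj <- unclass(model)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Load an FLD model from JSON
#'
#' @param path a file written by [fld_save_json].
#' @return An `fld_model`.
#' @export
fld_load_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  obj$v_c <- as.numeric(obj$v_c)
  obj$class_labels <- stats::setNames(unlist(obj$class_labels), c("A", "B"))
  structure(obj, class = "fld_model")
}
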