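# Synthetic image generators: (a) exact realizations of the one-lag
# recursion with chosen coefficients, so every estimator can be tested
# against known ground truth, and (b) cell-like scenes (bright clusters,
# Gaussian blur, Poisson-Gaussian noise) for end-to-end runs that do not
# depend on any deposited microscopy data.

# run `expr` under a fixed seed without disturbing the caller's RNG state
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

#' Stability of the one-lag recursion coefficients
#'
#' The recursion is a quarter-plane causal filter with transfer
#' denominator `A(z1, z2) = 1 - b01 z1 - b10 z2 - b11 z1 z2` (z1 along
#' columns, z2 along rows). By Huang's theorem it is stable iff
#' `A(z1, 0) != 0` on the closed unit disc (i.e. `|b01| < 1`) and
#' `A(z1, z2) != 0` for `|z1| = 1`, `|z2| <= 1`; the latter is checked by
#' requiring the root `z2 = (1 - b01 z1)/(b10 + b11 z1)` to stay outside
#' the closed unit disc on a fine grid of the unit circle.
#'
#' @param beta numeric 3-vector `(b01, b10, b11)`.
#' @param n_grid unit-circle grid resolution.
#' @return Logical.
#' @export
lag_recursion_stable <- function(beta, n_grid = 720L) {
  b01 <- beta[1]; b10 <- beta[2]; b11 <- beta[3]
  if (abs(b01) >= 1) return(FALSE)
  z1 <- exp(2i * pi * seq(0, 1, length.out = n_grid + 1L)[-1L])
  denom <- b10 + b11 * z1
  num <- 1 - b01 * z1
  deg <- Mod(denom) < 1e-12
  # degenerate denominator: A does not depend on z2, nonzero iff num != 0
  ok <- ifelse(deg, Mod(num) > 1e-12, Mod(num) > Mod(denom))
  all(ok)
}

#' Specification of a spatial-lag image simulation
#'
#' Describes a synthetic image generated by the one-lag recursion
#' `v[i,j] = b01 v[i,j-1] + b10 v[i-1,j] + b11 v[i-1,j-1] + e[i,j]`
#' with iid Gaussian innovations and an iid Gaussian first row and column.
#'
#' @param shape integer pair `(m, n)`.
#' @param beta numeric 3-vector `(b01, b10, b11)`.
#' @param innovation_sd standard deviation of the innovations `e`.
#' @param boundary_mean,boundary_sd distribution of the first row/column.
#' @param seed RNG seed; the output is fully determined by it.
#' @param clip_nonnegative clamp negative pixels at 0 (off by default;
#'   clipping breaks exact coefficient recovery).
#' @param allow_unstable skip the stability advisory
#'   `|b01| + |b10| + |b11| < 1`.
#' @return A list of class `lag_sim_spec`.
#' @export
lag_sim_spec <- function(shape = c(256, 256), beta = c(0.6443, 0.6674, -0.3438),
                         innovation_sd = 5, boundary_mean = 100,
                         boundary_sd = 5, seed = 1L,
                         clip_nonnegative = FALSE, allow_unstable = FALSE) {
  stopifnot(length(shape) == 2L, all(shape >= 2), length(beta) == 3L,
            innovation_sd >= 0, boundary_sd >= 0)
  if (!allow_unstable && !lag_recursion_stable(beta)) {
    stop(sprintf("unstable coefficients (b01, b10, b11) = (%.4f, %.4f, %.4f): the recursion diverges (set allow_unstable = TRUE to override)",
                 beta[1], beta[2], beta[3]), call. = FALSE)
  }
  structure(
    list(shape = as.integer(shape), beta = as.numeric(beta),
         innovation_sd = innovation_sd, boundary_mean = boundary_mean,
         boundary_sd = boundary_sd, seed = as.integer(seed),
         clip_nonnegative = isTRUE(clip_nonnegative)),
    class = c("lag_sim_spec", "sim_spec")
  )
}

#' Simulate an image from the spatial-lag recursion
#'
#' Draws the first row and column iid from the boundary distribution and
#' fills the interior in raster order by the one-lag recursion. Each row's
#' dependence on its left neighbour is an AR(1) sweep, evaluated with
#' `stats::filter`, so the construction is exact and fast.
#'
#' @param spec a [lag_sim_spec].
#' @param seed optional seed overriding `spec$seed`.
#' @return A [grayscale_image].
#' @export
simulate_lag_image <- function(spec, seed = NULL) {
  stopifnot(inherits(spec, "lag_sim_spec"))
  if (is.null(seed)) seed <- spec$seed
  m <- spec$shape[1]; n <- spec$shape[2]
  b <- spec$beta
  px <- with_seed(seed, {
    v <- matrix(0, m, n)
    v[1, ] <- stats::rnorm(n, spec$boundary_mean, spec$boundary_sd)
    v[, 1] <- stats::rnorm(m, spec$boundary_mean, spec$boundary_sd)
    e <- matrix(stats::rnorm((m - 1) * (n - 1), 0, spec$innovation_sd),
                m - 1, n - 1)
    for (i in 2:m) {
      drive <- b[2] * v[i - 1, 2:n] + b[3] * v[i - 1, 1:(n - 1)] + e[i - 1, ]
      v[i, 2:n] <- stats::filter(drive, b[1], method = "recursive",
                                 init = v[i, 1])
    }
    v
  })
  if (spec$clip_nonnegative) px <- pmax(px, 0)
  grayscale_image(px)
}

#' Specification of a cell-like scene simulation
#'
#' Bright clusters on a uniform background, blurred by a Gaussian point
#' spread function, with Poisson shot noise and additive Gaussian read
#' noise. Emulates the gross appearance of TIRF membrane-protein images;
#' it is not a calibrated optics model.
#'
#' @param shape integer pair `(m, n)`.
#' @param n_clusters number of bright spots.
#' @param cluster_intensity mean peak intensity added per cluster
#'   (exponentially distributed around this mean).
#' @param cluster_radius mean cluster radius in pixels (uniform in
#'   `[0.5, 1.5] x` this value).
#' @param psf_sigma Gaussian blur width in pixels.
#' @param background_level constant background intensity.
#' @param read_noise_sd additive Gaussian noise standard deviation.
#' @param shot_noise apply Poisson resampling of pixel intensities.
#' @param seed RNG seed.
#' @return A list of class `scene_sim_spec`.
#' @export
scene_sim_spec <- function(shape = c(256, 256), n_clusters = 150,
                           cluster_intensity = 400, cluster_radius = 3,
                           psf_sigma = 1.5, background_level = 100,
                           read_noise_sd = 3, shot_noise = TRUE, seed = 1L) {
  stopifnot(length(shape) == 2L, all(shape >= 2), n_clusters >= 0,
            background_level >= 0, psf_sigma >= 0)
  structure(
    list(shape = as.integer(shape), n_clusters = as.integer(n_clusters),
         cluster_intensity = cluster_intensity,
         cluster_radius = cluster_radius, psf_sigma = psf_sigma,
         background_level = background_level, read_noise_sd = read_noise_sd,
         shot_noise = isTRUE(shot_noise), seed = as.integer(seed)),
    class = c("scene_sim_spec", "sim_spec")
  )
}

# separable Gaussian blur with edge renormalization
gaussian_blur <- function(mat, sigma) {
  if (sigma <= 0) return(mat)
  r <- max(1L, ceiling(3 * sigma))
  kern <- stats::dnorm(-r:r, sd = sigma)
  kern <- kern / sum(kern)
  conv1 <- function(x) {
    n <- length(x)
    padded <- c(rep(x[1], r), x, rep(x[n], r))
    drop(stats::filter(padded, kern, sides = 2))[(r + 1):(r + n)]
  }
  out <- apply(mat, 2L, conv1)
  t(apply(out, 1L, conv1))
}

#' Simulate a cell-like scene
#'
#' @param spec a [scene_sim_spec].
#' @param seed optional seed overriding `spec$seed`.
#' @return A [grayscale_image]; intensities are non-negative.
#' @export
simulate_cell_scene <- function(spec, seed = NULL) {
  stopifnot(inherits(spec, "scene_sim_spec"))
  if (is.null(seed)) seed <- spec$seed
  m <- spec$shape[1]; n <- spec$shape[2]
  px <- with_seed(seed, {
    scene <- matrix(spec$background_level, m, n)
    if (spec$n_clusters > 0) {
      ci <- stats::runif(spec$n_clusters, 1, m)
      cj <- stats::runif(spec$n_clusters, 1, n)
      amp <- stats::rexp(spec$n_clusters, 1 / spec$cluster_intensity)
      rad <- stats::runif(spec$n_clusters, 0.5, 1.5) * spec$cluster_radius
      ii <- row(scene); jj <- col(scene)
      for (c_ in seq_len(spec$n_clusters)) {
        d2 <- (ii - ci[c_])^2 + (jj - cj[c_])^2
        scene <- scene + amp[c_] * (d2 <= rad[c_]^2)
      }
    }
    scene <- gaussian_blur(scene, spec$psf_sigma)
    if (spec$shot_noise) {
      scene <- matrix(stats::rpois(m * n, lambda = pmax(scene, 0)), m, n)
    }
    if (spec$read_noise_sd > 0) {
      scene <- scene + matrix(stats::rnorm(m * n, 0, spec$read_noise_sd), m, n)
    }
    pmax(scene, 0)
  })
  grayscale_image(px)
}

#' Simulate one image from a simulation spec
#'
#' Generic dispatcher over [lag_sim_spec] and [scene_sim_spec].
#'
#' @param spec a simulation spec.
#' @param seed optional seed override.
#' @return A [grayscale_image].
#' @export
simulate_image <- function(spec, seed = NULL) {
  if (inherits(spec, "lag_sim_spec")) simulate_lag_image(spec, seed)
  else if (inherits(spec, "scene_sim_spec")) simulate_cell_scene(spec, seed)
  else stop("`spec` must be a lag_sim_spec or scene_sim_spec", call. = FALSE)
}

#' Simulate a labelled two-class image set
#'
#' Generates `n_per_class` images from each spec with per-image seeds
#' derived deterministically from the master seed, so the whole collection
#' is reproducible and no two images share a seed.
#'
#' @param spec_A,spec_B simulation specs for the two classes.
#' @param n_per_class images per class, at least 2.
#' @param label_A,label_B class labels attached to the output.
#' @param seed master seed.
#' @return A list of class `sim_class_set`: `images` (list of
#'   [grayscale_image]), `labels`, `ids`, `seeds`.
#' @export
simulate_class_set <- function(spec_A, spec_B, n_per_class,
                               label_A = "A", label_B = "B", seed = 1L) {
  stopifnot(n_per_class >= 2)
  total <- 2L * n_per_class
  seeds <- with_seed(seed, sample.int(.Machine$integer.max - 1L, total))
  labels <- rep(c(label_A, label_B), each = n_per_class)
  ids <- sprintf("%s_%03d", labels, rep(seq_len(n_per_class), 2))
  images <- vector("list", total)
  for (r in seq_len(total)) {
    spec <- if (r <= n_per_class) spec_A else spec_B
    images[[r]] <- simulate_image(spec, seed = seeds[r])
  }
  structure(list(images = images, labels = labels, ids = ids, seeds = seeds),
            class = "sim_class_set")
}
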