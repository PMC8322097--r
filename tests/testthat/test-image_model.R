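# Spatial-lag model: vectorization, design construction, OLS estimation,
# lag-order selection, reconstruction.

test_that("vectorize_image flattens column-major and validates input", {
  px <- matrix(c("a" = 1, 2, 3, 4), 2, 2, byrow = TRUE)  # rows (1,2),(3,4)
  expect_equal(vectorize_image(px), c(1, 3, 2, 4))
  m <- 7; n <- 5
  img <- grayscale_image(matrix(runif(m * n), m, n))
  v <- vectorize_image(img)
  expect_length(v, m * n)
  # output[j*m + i] == pixels[i, j] in 0-based indexing
  expect_equal(v[3 * m + 2 + 1], img$pixels[3, 4])
  expect_error(grayscale_image(matrix(c(1, NA, 3, 4), 2, 2)), "non-finite")
  expect_error(grayscale_image(matrix(numeric(0), 0, 0)), "non-empty")
})

test_that("lag_structure enumerates offsets in the documented order", {
  l1 <- lag_structure(1)
  expect_identical(unname(l1$offsets),
                   matrix(c(0L, 1L, 1L, 0L, 1L, 1L), 3, 2, byrow = TRUE))
  for (L in 1:3) expect_equal(lag_structure(L)$k, (L + 1)^2 - 1)
  expect_error(lag_structure(0), "positive")
})

test_that("build_lagged_design matches brute-force enumeration", {
  # 3x3 image with pixels[i,j] = 3i + j + 1 (0-based), values 1..9 by row
  px <- matrix(1:9, 3, 3, byrow = TRUE)
  d <- build_lagged_design(px, lag_structure(1))
  expect_equal(d$response, c(5, 8, 6, 9))
  ora <- oracle_design(px, 1L)
  expect_equal(d$response, ora$y)
  expect_equal(unname(d$design), unname(ora$X))
  # left neighbour column is v[i, j-1] over the valid region
  expect_equal(unname(d$design[, "b01"]), c(4, 7, 5, 8))

  # random images, both lag orders
  set.seed(11)
  for (L in 1:2) {
    px <- matrix(rnorm(8 * 6), 8, 6)
    d <- build_lagged_design(px, lag_structure(L))
    ora <- oracle_design(px, L)
    expect_equal(d$n_samples, (8 - L) * (6 - L))
    expect_equal(d$response, ora$y)
    expect_equal(unname(d$design), unname(ora$X))
  }

  # a 280x280 image at one lag gives 279*279 samples and 3 columns
  px <- matrix(runif(280 * 280), 280, 280)
  d <- build_lagged_design(px)
  expect_equal(d$n_samples, 77841)
  expect_equal(ncol(d$design), 3)

  # shifts of a constant image all equal the response
  dc <- build_lagged_design(matrix(5, 4, 4))
  expect_true(all(dc$design == dc$response))

  expect_error(build_lagged_design(matrix(1:4, 2, 2), lag_structure(2)),
               "empty design")
})

test_that("fit_ols recovers exact coefficients on noise-free recursions", {
  beta <- c(0.6, 0.3, 0.05)
  img <- zero_noise_image(beta = beta)
  fit <- fit_ols(build_lagged_design(img))
  expect_equal(unname(fit$beta), beta, tolerance = 1e-8)
  expect_equal(fit$r_squared_uncentered, 1, tolerance = 1e-10)
  # identity: residuals + fitted == response exactly
  d <- build_lagged_design(img)
  expect_identical(fit$fitted + fit$residuals, d$response)
})

test_that("fit_ols matches the loop-based oracle on small images", {
  set.seed(21)
  for (rep in 1:5) {
    px <- matrix(runif(10 * 9, 50, 150), 10, 9)
    fit <- fit_ols(build_lagged_design(px))
    ora <- oracle_ols(px)
    expect_equal(unname(fit$beta), ora$beta, tolerance = 1e-8)
    expect_equal(unname(fit$white_cov), ora$white_cov, tolerance = 1e-8)
    expect_equal(unname(fit$t_stats), ora$t_stats, tolerance = 1e-8)
    expect_equal(fit$r_squared_uncentered, ora$r2_uncentered, tolerance = 1e-10)
  }
})

test_that("fit_ols reports informative failures", {
  expect_error(fit_ols(build_lagged_design(matrix(7, 6, 6))),
               "collinear.*b01", ignore.case = TRUE)
  # N = 1 <= k = 8 at L = 2 on a 3x3 image
  expect_error(fit_ols(build_lagged_design(matrix(rnorm(9), 3, 3),
                                           lag_structure(2))),
               "insufficient samples")
  expect_error(fit_ols(list()), "build_lagged_design")
})

test_that("select_lag_order keeps one lag for a strong one-lag process", {
  spec <- lag_sim_spec(shape = c(96, 96), beta = okt3_beta, seed = 5)
  fit <- select_lag_order(simulate_lag_image(spec), max_order = 2)
  expect_equal(fit$lag_order, 1)
  expect_true(all(fit$p_values < 0.05))
  expect_true(fit$significant)
  expect_true(fit$wald_significant)
})

test_that("select_lag_order flags white noise as insignificant", {
  set.seed(8)
  img <- grayscale_image(matrix(rnorm(200 * 200), 200, 200))
  fit <- select_lag_order(img, max_order = 3)
  expect_equal(fit$lag_order, 1)
  expect_false(fit$significant)
})

test_that("reconstruct_model_image shrinks by the lag and is exact in-sample", {
  img <- zero_noise_image(m = 30, n = 26)
  fit <- fit_ols(build_lagged_design(img))
  rec <- reconstruct_model_image(img, fit)
  expect_equal(dim(rec), c(29L, 25L))
  observed_valid <- img$pixels[2:30, 2:26]
  expect_equal(rec$pixels, observed_valid, tolerance = 1e-8)
  # model + residual image reproduces the observed valid region exactly
  spec <- lag_sim_spec(shape = c(40, 40), seed = 77)
  img2 <- simulate_lag_image(spec)
  fit2 <- fit_ols(build_lagged_design(img2))
  rec2 <- reconstruct_model_image(img2, fit2)
  resid_img <- matrix(fit2$residuals, 39, 39)
  expect_equal(rec2$pixels + resid_img, img2$pixels[2:40, 2:40],
               tolerance = 1e-12)
  expect_error(reconstruct_model_image(grayscale_image(matrix(1:12, 3, 4)), fit2),
               "shape mismatch")
})

test_that("estimates are scale invariant and transpose symmetric", {
  spec <- lag_sim_spec(shape = c(48, 40), seed = 13)
  img <- simulate_lag_image(spec)
  fit <- fit_ols(build_lagged_design(img))
  for (c_ in c(0.01, 3, 1e4)) {
    fit_c <- fit_ols(build_lagged_design(img$pixels * c_))
    expect_equal(fit_c$beta, fit$beta, tolerance = 1e-10)
    expect_equal(fit_c$t_stats, fit$t_stats, tolerance = 1e-10)
    expect_equal(fit_c$residuals, c_ * fit$residuals, tolerance = 1e-10)
  }
  fit_t <- fit_ols(build_lagged_design(t(img$pixels)))
  expect_equal(fit_t$beta[["b01"]], fit$beta[["b10"]], tolerance = 1e-10)
  expect_equal(fit_t$beta[["b10"]], fit$beta[["b01"]], tolerance = 1e-10)
  expect_equal(fit_t$beta[["b11"]], fit$beta[["b11"]], tolerance = 1e-10)
})
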