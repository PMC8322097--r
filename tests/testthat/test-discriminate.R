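# Fisher linear discriminant on class parameter matrices.

test_that("fld_fit recovers the separating direction for isotropic clouds", {
  set.seed(31)
  n <- 20000  # direction error decays ~ n^-1/2; the 1e-2 angle needs n this large
  A <- cbind(rnorm(n, 0, 0.01), rnorm(n, 0, 0.01), rnorm(n, 0, 0.01))
  B <- A + matrix(rep(c(1, 0, 0), each = n), n)  # shift along e1 only
  model <- fld_fit(A, B)
  angle <- acos(min(1, abs(sum(model$v_c * c(1, 0, 0)))))
  expect_lt(angle, 1e-2)
  expect_gt(model$proj_mean_B, model$proj_mean_A)
  expect_true(model$threshold > model$proj_mean_A &&
                model$threshold < model$proj_mean_B)
  expect_equal(sqrt(sum(model$v_c^2)), 1, tolerance = 1e-12)
  expect_equal(model$training_accuracy, 1)
})

test_that("fld_fit rejects degenerate classes", {
  X <- matrix(rnorm(30), 10, 3)
  expect_error(fld_fit(X, X), "degenerate")
  expect_error(fld_fit(X[1, , drop = FALSE], X), "at least 2")
  expect_error(fld_fit(X, matrix(rnorm(8), 2, 4)), "different parameter counts")
})

test_that("fld_project is the plain dot product and is consistent", {
  set.seed(32)
  A <- gaussian_cloud(30, pll_beta, pll_sd)
  B <- gaussian_cloud(30, okt3_beta, okt3_sd)
  model <- fld_fit(A, B)
  expect_equal(fld_project(model, rbind(c(0, 0, 0))), 0)
  expect_equal(mean(fld_project(model, A)), model$proj_mean_A,
               tolerance = 1e-12)
  expect_equal(mean(fld_project(model, B)), model$proj_mean_B,
               tolerance = 1e-12)
  row <- c(0.5, 0.6, -0.2)
  expect_equal(fld_project(model, rbind(row)), sum(row * model$v_c))
  expect_error(fld_project(model, matrix(1, 2, 5)), "dimension mismatch")
})

test_that("projections of Gaussian classes look normal", {
  set.seed(33)
  A <- gaussian_cloud(60, pll_beta, pll_sd)
  B <- gaussian_cloud(60, okt3_beta, okt3_sd)
  model <- fld_fit(A, B)
  # a linear image of a Gaussian is exactly Gaussian
  expect_true(ks_normality(fld_project(model, A))$pass)
  expect_true(ks_normality(fld_project(model, B))$pass)
})

test_that("fld_classify scores, breaks ties toward B, and counts hits", {
  model <- structure(
    list(v_c = c(1, 0, 0), class_labels = c(A = "low", B = "high"),
         proj_mean_A = -1, proj_mean_B = 1, proj_sd_A = 0.5, proj_sd_B = 0.5,
         threshold = 0, orientation = "B-high"),
    class = "fld_model")
  out <- fld_classify(model, c(-2, -0.1, 0, 0.1, 2),
                      true_labels = c("low", "low", "low", "high", "high"))
  expect_identical(out$labels, c("low", "low", "high", "high", "high"))
  expect_equal(out$accuracy, 4 / 5)
  expect_equal(unname(out$per_class_hits), c(2L, 2L))
  expect_equal(sum(out$confusion), 5)
  # perfectly separated projections classify perfectly
  perfect <- fld_classify(model, c(-3, -2, 1, 2),
                          true_labels = c("low", "low", "high", "high"))
  expect_equal(perfect$accuracy, 1)
})

test_that("swapping the classes only relabels", {
  set.seed(34)
  A <- gaussian_cloud(40, pll_beta, pll_sd)
  B <- gaussian_cloud(40, okt3_beta, okt3_sd)
  test <- rbind(gaussian_cloud(10, pll_beta, pll_sd),
                gaussian_cloud(10, okt3_beta, okt3_sd))
  m1 <- fld_fit(class_parameter_matrix(A, "PLL"),
                class_parameter_matrix(B, "OKT3"))
  m2 <- fld_fit(class_parameter_matrix(B, "OKT3"),
                class_parameter_matrix(A, "PLL"))
  expect_equal(m2$v_c, -m1$v_c, tolerance = 1e-10)
  l1 <- fld_classify(m1, fld_project(m1, test))$labels
  l2 <- fld_classify(m2, fld_project(m2, test))$labels
  expect_identical(l1, l2)
})

test_that("gaussian decision rule agrees with midpoint for equal spreads", {
  model <- structure(
    list(v_c = c(1, 0, 0), class_labels = c(A = "a", B = "b"),
         proj_mean_A = 0, proj_mean_B = 2, proj_sd_A = 1, proj_sd_B = 1,
         threshold = 1, orientation = "B-high"),
    class = "fld_model")
  x <- seq(-2, 4, by = 0.25)
  expect_identical(fld_classify(model, x, rule = "midpoint")$labels,
                   fld_classify(model, x, rule = "gaussian")$labels)
})

test_that("fld model JSON round-trips to identical projections", {
  set.seed(35)
  A <- gaussian_cloud(25, pll_beta, pll_sd)
  B <- gaussian_cloud(25, okt3_beta, okt3_sd)
  model <- fld_fit(A, B)
  path <- tempfile(fileext = ".json")
  on.exit(unlink(path))
  fld_save_json(model, path)
  back <- fld_load_json(path)
  expect_identical(back$class_labels, model$class_labels)
  expect_equal(fld_project(back, A), fld_project(model, A))
  expect_equal(back$threshold, model$threshold)
})
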