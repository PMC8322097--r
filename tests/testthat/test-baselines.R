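# Baseline statistics: spreading area, lognormal signal fit, KS normality,
# Kullback MDI comparison.

test_that("spreading_area counts strict exceedances and converts units", {
  img <- grayscale_image(matrix(0, 10, 10), pixel_size_nm = 73)
  expect_equal(spreading_area(img, 1)$pixel_count, 0)
  expect_equal(spreading_area(img, 1)$area_um2, 0)

  px <- matrix(0, 10, 10); px[4, 7] <- 10
  one <- spreading_area(grayscale_image(px, pixel_size_nm = 73), 5)
  expect_equal(one$pixel_count, 1)
  expect_equal(one$area_um2, 0.073^2)  # 0.005329 um^2

  # strict inequality at the threshold value itself
  expect_equal(spreading_area(grayscale_image(px), 10)$pixel_count, 0)
})

test_that("a rasterized disk has area close to pi r^2", {
  m <- 101
  px <- matrix(0, m, m)
  ctr <- (m + 1) / 2
  r <- 25
  d2 <- (row(px) - ctr)^2 + (col(px) - ctr)^2
  px[d2 <= r^2] <- 100
  got <- spreading_area(grayscale_image(px), 50)$pixel_count
  expect_equal(got, pi * r^2, tolerance = 0.02)
})

test_that("spreading_area is monotone non-increasing in the threshold", {
  set.seed(51)
  img <- grayscale_image(matrix(rlnorm(400, 4, 1), 20, 20))
  counts <- vapply(seq(0, 500, by = 25),
                   function(t) spreading_area(img, t)$pixel_count, 0)
  expect_true(all(diff(counts) <= 0))
})

test_that("signal_lognormal thresholds at 1.1 x median and fits the logs", {
  px <- matrix(100, 10, 10); px[1, 1:5] <- c(150, 200, 250, 300, 120)
  s <- signal_lognormal(grayscale_image(px))
  expect_equal(s$signal_threshold, 110)
  expect_true(s$insufficient_signal)  # only 5 pixels above 110

  # constant image: nothing above 1.1 x median
  sc <- signal_lognormal(grayscale_image(matrix(7, 8, 8)))
  expect_true(sc$insufficient_signal)
  expect_true(is.na(sc$lognormal_mu))

  # parameter recovery on a bright lognormal field over a dim background
  set.seed(52)
  n_sig <- 10000
  sig <- rlnorm(n_sig, meanlog = 5, sdlog = 0.4)
  bg <- runif(n_sig, 0, 1)  # median ~0.5, threshold ~0.55 excludes nothing bright
  px <- matrix(c(bg, sig), 200, 100)
  s2 <- signal_lognormal(grayscale_image(px))
  expect_false(s2$insufficient_signal)
  expect_equal(s2$lognormal_mu, 5, tolerance = 0.05 / 5)
  expect_equal(s2$lognormal_sigma, 0.4, tolerance = 0.05 / 0.4)
})

test_that("intensity scaling shifts mu by log(c) and leaves sigma alone", {
  set.seed(53)
  px <- matrix(rlnorm(2500, 3, 0.6), 50, 50)
  s1 <- signal_lognormal(grayscale_image(px))
  s2 <- signal_lognormal(grayscale_image(px * 7))
  expect_equal(s2$lognormal_mu, s1$lognormal_mu + log(7), tolerance = 1e-10)
  expect_equal(s2$lognormal_sigma, s1$lognormal_sigma, tolerance = 1e-10)
})

test_that("ks_normality behaves at both ends", {
  set.seed(54)
  pass_rate <- mean(vapply(1:40, function(s) {
    ks_normality(rnorm(20))$pass
  }, TRUE))
  expect_gt(pass_rate, 0.8)  # type-I error near nominal
  expect_false(ks_normality(runif(2000))$pass)  # power against a flat law
  expect_error(ks_normality(rep(3, 10)), "zero variance")
  expect_error(ks_normality(c(1, 2)), "at least 5")
})

test_that("kullback_mdi is symmetric, zero at equality, and powerful", {
  set.seed(55)
  a <- rnorm(20); b <- rnorm(20, 3)
  k1 <- kullback_mdi(a, b); k2 <- kullback_mdi(b, a)
  expect_equal(k1$statistic, k2$statistic, tolerance = 1e-12)
  expect_true(k1$reject_05)

  # identical fitted parameters give exactly zero divergence
  same <- kullback_mdi(a, a + 0)  # same mean and sd by construction
  expect_equal(same$divergence, 0, tolerance = 1e-12)
  expect_equal(same$statistic, 0, tolerance = 1e-12)
  expect_false(same$reject_05)

  expect_error(kullback_mdi(rep(1, 10), rnorm(10)), "zero variance")

  # null calibration: same distribution rejects at roughly the nominal rate
  rejections <- vapply(1:200, function(s) {
    kullback_mdi(rnorm(20), rnorm(20))$reject_05
  }, TRUE)
  expect_lt(mean(rejections), 0.15)
})
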