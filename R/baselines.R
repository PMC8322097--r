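# Baseline image statistics that the lag-model discrimination is compared
# against: threshold-based cell-spreading area, intensity summaries with a
# lognormal fit to above-background signal, a Kolmogorov-Smirnov normality
# check for parameter columns, and a Kullback minimum-discrimination-
# information test for comparing two projection sets.

#' Cell-spreading area by binary thresholding
#'
#' Labels each pixel 0/1 by a strict intensity threshold and converts the
#' above-threshold pixel count to an area using the pixel-size metadata.
#'
#' @param img a [grayscale_image] or numeric matrix.
#' @param threshold intensity cutoff; pixels strictly greater count.
#' @return A list of class `spreading_area`: `threshold`, `pixel_count`,
#'   `area_um2`.
#' @export
spreading_area <- function(img, threshold) {
  img <- as_grayscale_image(img)
  if (!is.finite(threshold)) stop("`threshold` must be finite", call. = FALSE)
  count <- sum(img$pixels > threshold)
  structure(
    list(threshold = threshold, pixel_count = count,
         area_um2 = count * (img$pixel_size_nm / 1000)^2),
    class = "spreading_area"
  )
}

#' Intensity summary with lognormal signal fit
#'
#' Signal pixels are those strictly above 1.1 times the image median (the
#' background estimate). The natural logs of the signal values give the
#' lognormal location `mu` (their mean) and scale `sigma` (their sample
#' standard deviation). With fewer than 30 signal pixels the fit is
#' flagged `insufficient_signal` and `mu`/`sigma` are `NA`.
#'
#' @param img a [grayscale_image] or numeric matrix.
#' @return A list of class `intensity_summary`: `mean_intensity`,
#'   `total_intensity`, `background_median`, `signal_threshold`
#'   (= 1.1 x median exactly), `n_signal`, `lognormal_mu`,
#'   `lognormal_sigma`, `insufficient_signal`.
#' @export
signal_lognormal <- function(img) {
  img <- as_grayscale_image(img)
  px <- img$pixels
  med <- stats::median(px)
  thr <- 1.1 * med
  sig <- px[px > thr]
  out <- list(
    mean_intensity = mean(px), total_intensity = sum(px),
    background_median = med, signal_threshold = thr,
    n_signal = length(sig),
    lognormal_mu = NA_real_, lognormal_sigma = NA_real_,
    insufficient_signal = length(sig) < 30L
  )
  if (!out$insufficient_signal) {
    if (any(sig <= 0)) {
      stop("signal pixels must be positive for a lognormal fit", call. = FALSE)
    }
    lg <- log(sig)
    out$lognormal_mu <- mean(lg)
    out$lognormal_sigma <- stats::sd(lg)
  }
  structure(out, class = "intensity_summary")
}

#' Kolmogorov-Smirnov normality check
#'
#' One-sample KS test of the values against a normal with the sample's own
#' mean and standard deviation. The plain KS p-value is reported (no
#' Lilliefors correction), which makes the test conservative; `pass` means
#' `p >= 0.05`.
#'
#' @param values numeric vector, `n >= 5`, non-degenerate.
#' @return List with `statistic`, `p_value`, `pass`, `n`.
#' @export
ks_normality <- function(values) {
  values <- as.numeric(values)
  if (length(values) < 5L) stop("need at least 5 values", call. = FALSE)
  s <- stats::sd(values)
  if (!is.finite(s) || s == 0) {
    stop("degenerate input: zero variance", call. = FALSE)
  }
  kt <- suppressWarnings(
    stats::ks.test(values, "pnorm", mean = mean(values), sd = s)
  )
  list(statistic = unname(kt$statistic), p_value = kt$p.value,
       pass = kt$p.value >= 0.05, n = length(values))
}

#' Kullback minimum discrimination information test for two projection sets
#'
#' Fits a normal to each set and computes the symmetric Kullback-Leibler
#' divergence
#' \deqn{J = \tfrac12\left(\frac{s_A^2}{s_B^2} + \frac{s_B^2}{s_A^2}\right)
#'   - 1 + \tfrac12 (m_A - m_B)^2
#'   \left(\frac{1}{s_A^2} + \frac{1}{s_B^2}\right),}
#' scaled by the effective sample size `nA * nB / (nA + nB)` and referred
#' to a chi-square distribution with 2 degrees of freedom (mean and
#' variance). The scaling makes the statistic asymptotically chi-square(2)
#' under equal distributions, so a same-class comparison rejects at the
#' nominal rate. This construction is one explicit reading of an
#' under-specified classical statistic; see the methods vignette.
#'
#' @param proj_A,proj_B numeric vectors, each `n >= 5`, non-degenerate.
#' @return List with `statistic`, `p_value`, `divergence` (J), `reject_05`,
#'   `n_A`, `n_B`.
#' @export
kullback_mdi <- function(proj_A, proj_B) {
  a <- as.numeric(proj_A); b <- as.numeric(proj_B)
  if (length(a) < 5L || length(b) < 5L) stop("need at least 5 values per set",
                                             call. = FALSE)
  sa <- stats::sd(a); sb <- stats::sd(b)
  if (!is.finite(sa) || !is.finite(sb) || sa == 0 || sb == 0) {
    stop("degenerate input: zero variance", call. = FALSE)
  }
  va <- sa^2; vb <- sb^2
  dm <- mean(a) - mean(b)
  J <- (va / vb + vb / va) / 2 - 1 + dm^2 * (1 / va + 1 / vb) / 2
  n_eff <- length(a) * length(b) / (length(a) + length(b))
  stat <- n_eff * J
  p <- stats::pchisq(stat, df = 2, lower.tail = FALSE)
  list(statistic = stat, p_value = p, divergence = J, reject_05 = p < 0.05,
       n_A = length(a), n_B = length(b))
}
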