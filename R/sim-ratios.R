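#' Generate AC/DC ratios from true Hb under the optical model
#'
#' The generative inverse of the published two-wavelength regression: each
#' fractional AC/DC ratio is affine in Hb, `r = k * Hb + c`, plus optional
#' Gaussian ratio noise. With the default calibration and zero noise,
#' applying the published model to the generated pair returns the input Hb
#' exactly (to floating-point precision).
#'
#' @param hb_true Positive numeric vector of true Hb values (g/L).
#' @param optical An [optical_model()].
#' @param seed Optional integer seed for the ratio noise.
#'
#' @return A tibble with columns `hb_true_gL`, `ratio_red`, `ratio_inf`
#'   (dimensionless fractions).
#' @examples
#' r <- ratios_from_hb(83.78, optical_model(ratio_noise_sd = 0))
#' 341.84 * r$ratio_red + 569.61 * r$ratio_inf + 49.87  # 83.78
#' @export
ratios_from_hb <- function(hb_true, optical = optical_model(), seed = NULL) {
  stopifnot(inherits(optical, "optical_model"))
  if (any(!is.finite(hb_true)) || any(hb_true <= 0)) {
    abort("`hb_true` must be positive and finite.")
  }
  with_seed(seed, {
    n <- length(hb_true)
    tibble::tibble(
      hb_true_gL = hb_true,
      ratio_red = optical$k_red * hb_true + optical$c_red +
        rnorm(n, 0, optical$ratio_noise_sd),
      ratio_inf = optical$k_inf * hb_true + optical$c_inf +
        rnorm(n, 0, optical$ratio_noise_sd)
    )
  })
}

#' Metric-level paired dataset calibrated to the study marginals
#'
#' Draws the two fractional AC/DC ratios from a bivariate normal whose
#' marginal means/SDs default to the study population values (red
#' 3.13% +/- 1.35%, infrared 3.73% +/- 1.45%, expressed as fractions) with
#' inter-ratio correlation `ratio_corr`, then generates the reference Hb from
#' the published two-wavelength model plus Gaussian residual noise. This is
#' the generator used for coefficient-recovery experiments: the published
#' coefficients are its ground truth. DC voltages are drawn from truncated
#' normals matching the study's per-channel levels and the AC voltages are
#' reconstructed as `ratio * DC`.
#'
#' @param n Number of paired samples (at least 3).
#' @param ratio_means,ratio_sds Length-2 numerics (red, infrared), fractional
#'   ratio marginals.
#' @param ratio_corr Correlation between the two ratios.
#' @param hb_noise_sd Residual SD of Hb around the model surface (g/L).
#'   The default 9.7 reproduces a model-reference correlation of about 0.81
#'   at the study's Hb SD (16.55 * sqrt(1 - 0.81^2) = 9.7).
#' @param optical An [optical_model()] supplying the DC voltage levels.
#' @param n_pigs Number of animal ids to spread the rows over (contiguous
#'   blocks, used by repeated-measures analyses).
#' @param seed Optional integer seed.
#'
#' @return A tibble with columns `pig_id`, `stage`, `step_index`,
#'   `hb_ref_gL`, `ac_red_v`, `dc_red_v`, `ac_inf_v`, `dc_inf_v`,
#'   `ratio_red`, `ratio_inf`.
#' @examples
#' d <- metric_dataset(376, seed = 1)
#' round(colMeans(d[, c("ratio_red", "ratio_inf")]), 4)
#' @export
metric_dataset <- function(n = 376,
                           ratio_means = c(RATIO_RED_MEAN, RATIO_INF_MEAN),
                           ratio_sds = c(RATIO_RED_SD, RATIO_INF_SD),
                           ratio_corr = 0.7,
                           hb_noise_sd = 9.7,
                           optical = optical_model(),
                           n_pigs = 19,
                           seed = NULL) {
  if (n < 3) abort("`n` must be at least 3 (no estimable moments below that).")
  stopifnot(length(ratio_means) == 2, length(ratio_sds) == 2)
  with_seed(seed, {
    r <- rbvnorm(n, mean = ratio_means, sd = ratio_sds, rho = ratio_corr)
    hb <- PUB_COEF_RED * r[, 1] + PUB_COEF_INF * r[, 2] + PUB_INTERCEPT +
      rnorm(n, 0, hb_noise_sd)
    dc_red <- rnorm_trunc(n, optical$dc_red_v, 5.24, lower = 0.27, upper = 17.71)
    dc_inf <- rnorm_trunc(n, optical$dc_inf_v, 3.03, lower = 0.05)
    pig <- rep(seq_len(n_pigs), length.out = ceiling(n / n_pigs) * n_pigs)
    pig <- sort(pig)[seq_len(n)]
    tibble::tibble(
      pig_id = pig,
      stage = "hemodilution",
      step_index = as.integer(stats::ave(pig, pig, FUN = seq_along)),
      hb_ref_gL = hb,
      ac_red_v = r[, 1] * dc_red,
      dc_red_v = dc_red,
      ac_inf_v = r[, 2] * dc_inf,
      dc_inf_v = dc_inf,
      ratio_red = r[, 1],
      ratio_inf = r[, 2]
    )
  })
}

#' Paired dataset with a prescribed difference distribution
#'
#' Fixture generator for agreement analyses: reference Hb is drawn from the
#' study marginal (normal with mean 83.78 g/L, SD 16.55 g/L, truncated to
#' [51, 143]) and the test method is the reference plus a normal difference
#' with the given bias and SD.
#'
#' @param bias Mean of `hb_test - hb_ref` (g/L).
#' @param sd SD of the differences (g/L), non-negative.
#' @param n Number of pairs (at least 2).
#' @param n_subjects Number of subject ids to spread rows over.
#' @param seed Optional integer seed.
#'
#' @return A tibble with columns `pig_id`, `hb_ref_gL`, `hb_test_gL`.
#' @examples
#' d <- difference_dataset(bias = 1.69, sd = 14.13, n = 376, seed = 1)
#' mean(d$hb_test_gL - d$hb_ref_gL)
#' @export
difference_dataset <- function(bias, sd, n, n_subjects = 19, seed = NULL) {
  if (sd < 0) abort("`sd` must be non-negative.")
  if (n < 2) abort("`n` must be at least 2.")
  with_seed(seed, {
    ref <- rnorm_trunc(n, HB_MEAN, HB_SD, lower = HB_MIN, upper = HB_MAX)
    diffs <- rnorm(n, bias, sd)
    pig <- sort(rep(seq_len(n_subjects), length.out = n))
    tibble::tibble(
      pig_id = pig,
      hb_ref_gL = ref,
      hb_test_gL = ref + diffs
    )
  })
}

#' Bivariate-normal pairs with a prescribed population correlation
#'
#' Fixture generator for correlation-recovery experiments: draws
#' (`ratio_red`, `hb_ref_gL`) pairs from a bivariate normal whose marginals
#' default to the study values of the red AC/DC ratio and the reference Hb,
#' with population correlation `rho`.
#'
#' @param n Number of pairs.
#' @param rho Population correlation, in (-1, 1).
#' @param mean_x,sd_x Marginal of the first variable (fractional ratio).
#' @param mean_y,sd_y Marginal of the second variable (g/L).
#' @param seed Optional integer seed.
#'
#' @return A tibble with columns `ratio_red`, `hb_ref_gL`.
#' @export
correlation_dataset <- function(n, rho,
                                mean_x = RATIO_RED_MEAN, sd_x = RATIO_RED_SD,
                                mean_y = HB_MEAN, sd_y = HB_SD,
                                seed = NULL) {
  stopifnot(abs(rho) < 1, n >= 3)
  with_seed(seed, {
    m <- rbvnorm(n, mean = c(mean_x, mean_y), sd = c(sd_x, sd_y), rho = rho)
    tibble::tibble(ratio_red = m[, 1], hb_ref_gL = m[, 2])
  })
}
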