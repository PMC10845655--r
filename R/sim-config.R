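# Fixed two-wavelength regression published for the descending-aortic PPG
# hemoglobin model: Hb = 341.84 * ratio_red + 569.61 * ratio_inf + 49.87,
# with both AC/DC ratios expressed as dimensionless fractions.
PUB_COEF_RED <- 341.84
PUB_COEF_INF <- 569.61
PUB_INTERCEPT <- 49.87

# Calibration targets for metric-level simulation (study-population marginals):
# AC/DC ratios as fractions, Hb in g/L.
RATIO_RED_MEAN <- 0.0313
RATIO_RED_SD <- 0.0135
RATIO_INF_MEAN <- 0.0373
RATIO_INF_SD <- 0.0145
HB_MEAN <- 83.78
HB_SD <- 16.55
HB_MIN <- 51
HB_MAX <- 143

#' Simulation configuration for the hemodilution-transfusion protocol
#'
#' Bundles every parameter of the synthetic study: animal population, the
#' stepwise isovolemic hemodilution / transfusion protocol, the waveform
#' recorder, and the noise model. Defaults emulate the porcine study the
#' pipeline is designed around: 19 pigs of 33 +/- 3.5 kg, blood withdrawn in
#' 50-mL aliquots with isovolemic fluid replacement until the reference Hb
#' falls below 60 g/L, then stepwise reinfusion; two-channel recording at
#' 500 Hz with 16-bit quantisation.
#'
#' @param n_pigs Number of animals.
#' @param baseline_hb_mean,baseline_hb_sd Between-animal distribution of the
#'   pre-dilution Hb (g/L).
#' @param withdrawal_step_ml Blood withdrawn (and later reinfused) per
#'   protocol step (mL); one paired sample is taken after each step.
#' @param fluid_ml_per_step Additional isovolemic crystalloid/colloid exchange
#'   per step (mL) on top of the replaced withdrawal volume; models the
#'   maintenance and replacement fluids running between samples. The effective
#'   exchange per sampled step is `withdrawal_step_ml + fluid_ml_per_step`.
#' @param blood_volume_ml_per_kg Circulating blood volume per body mass.
#' @param weight_mean_kg,weight_sd_kg Animal body-mass distribution.
#' @param hemodilution_stop_gL Dilution stops once true Hb drops below this
#'   threshold (g/L); transfusion (reinfusion) then runs the same number of
#'   steps in reverse.
#' @param hr_range_bpm Length-2 numeric, admissible heart-rate range.
#' @param hr_mean_bpm,hr_sd_bpm Between-animal heart-rate distribution,
#'   truncated to `hr_range_bpm`.
#' @param fs_hz Sampling rate of the waveform recorder (Hz).
#' @param adc_bits Quantisation depth of the recorder.
#' @param adc_range_v Length-2 numeric, recorder voltage range (V).
#' @param ratio_corr Correlation between the red and infrared AC/DC ratios in
#'   metric-level simulation.
#' @param hb_residual_sd_gL SD of the per-sample deviation of true Hb around
#'   the deterministic dilution trajectory (g/L).
#' @param ref_noise_sd_gL SD of the reference (blood-gas analyser) measurement
#'   noise (g/L).
#' @param seed Default seed used by generators consuming this config; `NULL`
#'   leaves the RNG stream untouched.
#'
#' @return An object of class `sim_config` (a named list).
#' @examples
#' cfg <- sim_config(n_pigs = 2, seed = 1)
#' cfg$n_pigs
#' @export
sim_config <- function(n_pigs = 19,
                       baseline_hb_mean = 90,
                       baseline_hb_sd = 13,
                       withdrawal_step_ml = 50,
                       fluid_ml_per_step = 50,
                       blood_volume_ml_per_kg = 70,
                       weight_mean_kg = 33,
                       weight_sd_kg = 3.5,
                       hemodilution_stop_gL = 60,
                       hr_range_bpm = c(56, 159),
                       hr_mean_bpm = 95,
                       hr_sd_bpm = 19,
                       fs_hz = 500,
                       adc_bits = 16,
                       adc_range_v = c(0, 20),
                       ratio_corr = 0.7,
                       hb_residual_sd_gL = 1.5,
                       ref_noise_sd_gL = 2,
                       seed = NULL) {
  cfg <- list(
    n_pigs = n_pigs,
    baseline_hb_mean = baseline_hb_mean,
    baseline_hb_sd = baseline_hb_sd,
    withdrawal_step_ml = withdrawal_step_ml,
    fluid_ml_per_step = fluid_ml_per_step,
    blood_volume_ml_per_kg = blood_volume_ml_per_kg,
    weight_mean_kg = weight_mean_kg,
    weight_sd_kg = weight_sd_kg,
    hemodilution_stop_gL = hemodilution_stop_gL,
    hr_range_bpm = as.numeric(hr_range_bpm),
    hr_mean_bpm = hr_mean_bpm,
    hr_sd_bpm = hr_sd_bpm,
    fs_hz = fs_hz,
    adc_bits = as.integer(adc_bits),
    adc_range_v = as.numeric(adc_range_v),
    ratio_corr = ratio_corr,
    hb_residual_sd_gL = hb_residual_sd_gL,
    ref_noise_sd_gL = ref_noise_sd_gL,
    seed = seed
  )
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
}

validate_sim_config <- function(cfg) {
  if (cfg$n_pigs < 1) abort("`n_pigs` must be at least 1.")
  if (cfg$baseline_hb_mean <= 0) abort("`baseline_hb_mean` must be positive.")
  if (cfg$withdrawal_step_ml <= 0) abort("`withdrawal_step_ml` must be positive.")
  if (cfg$fluid_ml_per_step < 0) abort("`fluid_ml_per_step` must be non-negative.")
  if (cfg$blood_volume_ml_per_kg <= 0 || cfg$weight_mean_kg <= 0) {
    abort("Blood volume must be positive: check `blood_volume_ml_per_kg` and `weight_mean_kg`.")
  }
  if (cfg$hemodilution_stop_gL <= 0 || cfg$hemodilution_stop_gL >= cfg$baseline_hb_mean) {
    abort("`hemodilution_stop_gL` must lie in (0, baseline_hb_mean).")
  }
  if (cfg$fs_hz <= 0) abort("`fs_hz` must be positive.")
  if (cfg$ratio_corr < 0 || cfg$ratio_corr >= 1) {
    abort("`ratio_corr` must lie in [0, 1).")
  }
  if (length(cfg$hr_range_bpm) != 2 || diff(cfg$hr_range_bpm) <= 0 ||
      cfg$hr_range_bpm[1] <= 0) {
    abort("`hr_range_bpm` must be an increasing positive pair.")
  }
  if (length(cfg$adc_range_v) != 2 || diff(cfg$adc_range_v) <= 0) {
    abort("`adc_range_v` must be an increasing pair.")
  }
  cfg
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>\n")
  cat(sprintf("  %d pig(s), baseline Hb %.1f +/- %.1f g/L, stop < %.0f g/L\n",
              x$n_pigs, x$baseline_hb_mean, x$baseline_hb_sd,
              x$hemodilution_stop_gL))
  cat(sprintf("  step %.0f mL blood + %.0f mL fluid exchange, blood volume %.0f mL/kg\n",
              x$withdrawal_step_ml, x$fluid_ml_per_step,
              x$blood_volume_ml_per_kg))
  cat(sprintf("  recorder: %.0f Hz, %d-bit over [%.1f, %.1f] V\n",
              x$fs_hz, x$adc_bits, x$adc_range_v[1], x$adc_range_v[2]))
  invisible(x)
}

#' Two-wavelength optical model linking Hb to the AC/DC ratios
#'
#' Affine first-order Beer-Lambert model: the fractional AC/DC ratio at each
#' wavelength is `r = k * Hb + c` (plus optional Gaussian ratio noise). The
#' default calibration is the exact generative inverse of the published
#' two-wavelength regression, i.e. it satisfies
#' `341.84 * k_red + 569.61 * k_inf = 1` and
#' `341.84 * c_red + 569.61 * c_inf = -49.87`,
#' so that applying the published model to noise-free ratios returns the
#' generating Hb identically. The Hb signal is split equally between the two
#' wavelengths (`341.84 * k_red = 569.61 * k_inf = 0.5`); the offsets are
#' chosen so both ratios stay strictly positive over the protocol Hb range
#' (51-143 g/L).
#'
#' @param k_red,k_inf Slopes of the fractional ratio per g/L of Hb.
#' @param c_red,c_inf Dimensionless ratio offsets.
#' @param dc_red_v,dc_inf_v Mean DC voltage level per channel (V).
#' @param dc_red_sd_v,dc_inf_sd_v Between-record SD of the DC levels (V).
#' @param ratio_noise_sd SD of additive noise on each generated ratio
#'   (dimensionless fraction).
#' @param check If `TRUE` (default), reject calibrations that violate the two
#'   exact-inverse constraints beyond `1e-9`.
#'
#' @return An object of class `optical_model`.
#' @examples
#' om <- optical_model()
#' 341.84 * om$k_red + 569.61 * om$k_inf  # 1 by construction
#' @export
optical_model <- function(k_red = 0.5 / PUB_COEF_RED,
                          k_inf = 0.5 / PUB_COEF_INF,
                          c_red = -0.073,
                          c_inf = (-PUB_INTERCEPT - PUB_COEF_RED * c_red) / PUB_COEF_INF,
                          dc_red_v = 6.90,
                          dc_inf_v = 3.13,
                          dc_red_sd_v = 2.0,
                          dc_inf_sd_v = 1.0,
                          ratio_noise_sd = 0.002,
                          check = TRUE) {
  om <- list(k_red = k_red, k_inf = k_inf, c_red = c_red, c_inf = c_inf,
             dc_red_v = dc_red_v, dc_inf_v = dc_inf_v,
             dc_red_sd_v = dc_red_sd_v, dc_inf_sd_v = dc_inf_sd_v,
             ratio_noise_sd = ratio_noise_sd)
  class(om) <- "optical_model"
  if (k_red <= 0 || k_inf <= 0) {
    abort("Optical slopes must be positive: the AC/DC ratio increases with Hb.")
  }
  if (check) {
    e1 <- abs(PUB_COEF_RED * k_red + PUB_COEF_INF * k_inf - 1)
    e2 <- abs(PUB_COEF_RED * c_red + PUB_COEF_INF * c_inf + PUB_INTERCEPT)
    if (e1 > 1e-9 || e2 > 1e-9) {
      abort(paste0(
        "Optical calibration does not invert the published model: ",
        sprintf("slope constraint off by %.3g, offset constraint off by %.3g ", e1, e2),
        "(tolerance 1e-9). Set `check = FALSE` to use a non-invertible calibration."
      ))
    }
  }
  om
}

#' @export
print.optical_model <- function(x, ...) {
  cat("<optical_model>  r = k * Hb + c (fractional AC/DC)\n")
  cat(sprintf("  red: k = %.6g, c = %.6g; infrared: k = %.6g, c = %.6g\n",
              x$k_red, x$c_red, x$k_inf, x$c_inf))
  cat(sprintf("  DC levels %.2f / %.2f V, ratio noise sd %.4g\n",
              x$dc_red_v, x$dc_inf_v, x$ratio_noise_sd))
  invisible(x)
}
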