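# shared fixtures, built in code at test time

# deterministic single-pig config with no biological noise
noise_free_config <- function(baseline = 110, bv_per_kg = 70, weight = 33,
                              step = 50, fluid = 0, stop = 60) {
  sim_config(
    n_pigs = 1, baseline_hb_mean = baseline, baseline_hb_sd = 0,
    withdrawal_step_ml = step, fluid_ml_per_step = fluid,
    blood_volume_ml_per_kg = bv_per_kg,
    weight_mean_kg = weight, weight_sd_kg = 0,
    hemodilution_stop_gL = stop,
    hb_residual_sd_gL = 0, ref_noise_sd_gL = 0, seed = 1
  )
}

# clean synthetic record: no noise, no wander, no artifacts
clean_record <- function(ratio_red = 0.0313, ratio_inf = 0.0373,
                         hr_bpm = 72, duration_s = 20, seed = 1, ...) {
  waveform_synthesize(ratio_red, ratio_inf, hr_bpm = hr_bpm,
                      duration_s = duration_s, noise_sd_v = 0,
                      wander_frac = 0, seed = seed, ...)
}

# brute-force AUC oracle: fraction of (positive, negative) score pairs
# ordered correctly, ties counting one half; positives are high scores
auc_bruteforce <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  tot <- 0
  for (p in pos) for (q in neg) {
    tot <- tot + (p > q) + 0.5 * (p == q)
  }
  tot / (length(pos) * length(neg))
}
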