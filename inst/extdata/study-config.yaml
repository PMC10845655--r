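# Simulation config for the default hemodilution-transfusion study.
# Flat key/value schema: every key is an argument of dppghb::sim_config();
# the optional `optical:` block holds dppghb::optical_model() arguments.

n_pigs: 19                  # animals enrolled
baseline_hb_mean: 90        # g/L, pre-dilution Hb (between-animal mean)
baseline_hb_sd: 13          # g/L
withdrawal_step_ml: 50      # blood withdrawn per step; one sample per step
fluid_ml_per_step: 50       # extra isovolemic fluid exchange per step (mL)
blood_volume_ml_per_kg: 70
weight_mean_kg: 33
weight_sd_kg: 3.5
hemodilution_stop_gL: 60    # dilution stops once true Hb drops below this
hr_range_bpm: [56, 159]
hr_mean_bpm: 95
hr_sd_bpm: 19
fs_hz: 500                  # waveform recorder sampling rate
adc_bits: 16
adc_range_v: [0, 20]
ratio_corr: 0.7             # red-infrared ratio correlation (metric-level)
hb_residual_sd_gL: 1.5      # per-sample wobble around the dilution trajectory
ref_noise_sd_gL: 2          # reference (blood-gas) measurement noise
seed: 1

optical:
  # defaults are the exact generative inverse of the published model;
  # override only with calibrations satisfying the inverse constraints
  ratio_noise_sd: 0.002
  dc_red_v: 6.90
  dc_inf_v: 3.13
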