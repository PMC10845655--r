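test_that("dilution step count matches the closed-form exchange law", {
  # 110 g/L baseline, 2310 mL blood volume, 50 mL exchanged per step:
  # first k with 110 * (1 - 50/2310)^k < 60 is ceil(log(60/110)/log(1 - 50/2310)) = 28
  prot <- simulate_protocol(noise_free_config())
  expect_equal(sum(prot$stage == "hemodilution"), 28)
  expect_equal(sum(prot$stage == "transfusion"), 28)
  # trajectory crosses the stop threshold exactly once, at the last dilution step
  dil <- prot$hb_true_gL[prot$stage == "hemodilution"]
  expect_true(all(diff(dil) < 0))
  expect_lt(min(dil), 60)
  expect_true(all(dil[-length(dil)] >= 60))
  # transfusion retraces upward to baseline
  tx <- prot$hb_true_gL[prot$stage == "transfusion"]
  expect_true(all(diff(tx) > 0))
  expect_equal(max(tx), 110, tolerance = 1e-8)
})

test_that("animals whose baseline is below the stop threshold are flagged as empty runs", {
  cfg <- sim_config(n_pigs = 4, baseline_hb_mean = 62, baseline_hb_sd = 8,
                    hemodilution_stop_gL = 60, seed = 2)
  expect_warning(prot <- simulate_protocol(cfg), "empty runs flagged")
  expect_true(length(attr(prot, "empty_pigs")) >= 1)
  expect_false(any(attr(prot, "empty_pigs") %in% prot$pig_id))
})

test_that("default study scale and seeded determinism", {
  cfg <- sim_config(seed = 99)
  p1 <- suppressWarnings(simulate_protocol(cfg))
  p2 <- suppressWarnings(simulate_protocol(cfg))
  expect_identical(p1, p2)
  # roughly the study's bookkeeping: ~16-20+ pairs per pig, ~376 total
  expect_gt(nrow(p1), 250)
  expect_lt(nrow(p1), 520)
  expect_lt(min(p1$hb_true_gL), 60)
  # different seed, different draw
  p3 <- suppressWarnings(simulate_protocol(sim_config(seed = 100)))
  expect_false(isTRUE(all.equal(p1$hb_true_gL[1], p3$hb_true_gL[1])))
})

test_that("noise-free ratios invert the published model exactly", {
  om <- optical_model(ratio_noise_sd = 0)
  hb <- c(49.87, 51, 60, 83.78, 100, 143)
  r <- ratios_from_hb(hb, om)
  back <- predict(published_model(), r)
  expect_equal(back, hb, tolerance = 1e-12)
  # ratios stay physical over the protocol Hb range (51-143 g/L)
  rr <- ratios_from_hb(seq(51, 143, by = 0.5), om)
  expect_true(all(rr$ratio_red > 0 & rr$ratio_red < 1))
  expect_true(all(rr$ratio_inf > 0 & rr$ratio_inf < 1))
})

test_that("calibrations violating the exact-inverse constraints are rejected", {
  expect_error(optical_model(k_red = 0.002), "does not invert")
  expect_error(optical_model(c_red = -0.073, c_inf = 0), "does not invert")
  expect_error(optical_model(k_red = -0.001, check = FALSE), "positive")
  # explicit opt-out is allowed
  expect_s3_class(optical_model(k_red = 0.002, check = FALSE), "optical_model")
})

test_that("noisy ratio generation round-trips Hb on average", {
  om <- optical_model(ratio_noise_sd = 0.002)
  r <- ratios_from_hb(rep(100, 1000), om, seed = 7)
  back <- predict(published_model(), r)
  # noise propagated through the model: sd = sqrt(341.84^2 + 569.61^2) * 0.002
  se <- sqrt(341.84^2 + 569.61^2) * 0.002 / sqrt(1000)
  expect_lt(abs(mean(back) - 100), 3 * se)
})

test_that("metric_dataset reproduces the configured marginal moments", {
  d <- metric_dataset(10000, seed = 5)
  # red ratio mean 3.13% as a fraction, +/- 3 MC SE
  se_red <- 0.0135 / sqrt(10000)
  expect_lt(abs(mean(d$ratio_red) - 0.0313), 3 * se_red)
  se_inf <- 0.0145 / sqrt(10000)
  expect_lt(abs(mean(d$ratio_inf) - 0.0373), 3 * se_inf)
  # inter-ratio correlation near the configured 0.7
  se_rho <- (1 - 0.7^2) / sqrt(10000)
  expect_lt(abs(cor(d$ratio_red, d$ratio_inf) - 0.7), 3 * se_rho)
  expect_error(metric_dataset(2), "at least 3")
})

test_that("noise-free metric_dataset is perfectly collinear with Hb", {
  d <- metric_dataset(50, ratio_corr = 0.999, hb_noise_sd = 0, seed = 1)
  hb_model <- predict(published_model(), d)
  expect_equal(cor(hb_model, d$hb_ref_gL), 1, tolerance = 1e-12)
})

test_that("difference_dataset has the prescribed difference law and truncation", {
  expect_error(difference_dataset(0, -1, 10), "non-negative")
  expect_error(difference_dataset(0, 1, 1), "at least 2")
  d0 <- difference_dataset(0, 0, 10, seed = 1)
  expect_equal(d0$hb_test_gL, d0$hb_ref_gL)
  d <- difference_dataset(1.69, 14.13, 376 * 50, seed = 2)
  se <- 14.13 / sqrt(nrow(d))
  expect_lt(abs(mean(d$hb_test_gL - d$hb_ref_gL) - 1.69), 3 * se)
  expect_true(all(d$hb_ref_gL >= 51 & d$hb_ref_gL <= 143))
})

test_that("waveform construction fixes the pulsatile fraction and beat count", {
  rec <- clean_record(ratio_red = 0.2, ratio_inf = 0.2, dc_red_v = 2.0,
                      dc_inf_v = 2.0, hr_bpm = 60, duration_s = 10)
  # peak-to-trough of one beat of the raw signal = DC * ratio = 0.4 V
  fs <- rec$fs_hz
  beat <- rec$red_v[(2 * fs + 1):(3 * fs)]
  expect_equal(max(beat) - min(beat), 0.4, tolerance = 2e-3)
  # 10 beat periods in 10 s at 60 bpm: autocovariance peaks at 1-s lag
  expect_equal(length(rec$red_v), 10 * fs)
  # determinism
  rec2 <- clean_record(ratio_red = 0.2, ratio_inf = 0.2, dc_red_v = 2.0,
                       dc_inf_v = 2.0, hr_bpm = 60, duration_s = 10)
  expect_identical(rec$red_v, rec2$red_v)
})

test_that("waveform preconditions are enforced", {
  expect_error(waveform_synthesize(1.2, 0.04, hr_bpm = 70, duration_s = 10),
               "between 0 and 1")
  expect_error(waveform_synthesize(0.03, 0.04, hr_bpm = 20, duration_s = 10),
               "configured range")
  expect_error(waveform_synthesize(0.03, 0.04, hr_bpm = 60, duration_s = 2),
               "3 beat periods")
})

test_that("waveform text round-trips through the plain-text format", {
  rec <- clean_record(duration_s = 5, hr_bpm = 120)
  path <- withr::local_tempfile(fileext = ".txt")
  write_waveform(rec, path)
  back <- read_waveform(path)
  expect_equal(back$fs_hz, rec$fs_hz)
  expect_equal(back$adc_bits, rec$adc_bits)
  # quantized voltages survive the decimal text representation
  expect_equal(back$red_v, rec$red_v, tolerance = 1e-7)
  expect_equal(back$inf_v, rec$inf_v, tolerance = 1e-7)
  # header corruption is reported with its line
  lines <- readLines(path)
  lines[2] <- "bits\t16"
  writeLines(lines, path)
  expect_error(read_waveform(path), "line 2")
})

test_that("correlation_dataset attains the requested population correlation", {
  d <- correlation_dataset(20000, rho = 0.79, seed = 3)
  se <- (1 - 0.79^2) / sqrt(20000)
  expect_lt(abs(cor(d$ratio_red, d$hb_ref_gL) - 0.79), 3 * se)
})
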