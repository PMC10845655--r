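fs <- 500

test_that("bandpass filter rejects DC and respiratory wander, passes the cardiac band", {
  t <- (0:(20 * fs - 1)) / fs
  # constant input: DC gain is forced to exactly zero (outside start-up edges)
  y0 <- bandpass_filter(rep(2, length(t)), fs)
  core0 <- y0[(attr(y0, "edge") + 1):(length(y0) - attr(y0, "edge"))]
  expect_lt(max(abs(core0)) / 2, 1e-3)
  # 2 Hz unit sinusoid passes at unit gain (within ripple)
  y2 <- bandpass_filter(sin(2 * pi * 2 * t), fs)
  core <- y2[(5 * fs):(15 * fs)]
  expect_equal(max(core) - min(core), 2, tolerance = 0.01)
  # 0.2 Hz wander attenuated by at least 90%
  yw <- bandpass_filter(sin(2 * pi * 0.2 * t), fs)
  core_w <- yw[(5 * fs):(15 * fs)]
  expect_lt((max(core_w) - min(core_w)) / 2, 0.1)
})

test_that("filter preconditions are enforced", {
  expect_error(bandpass_filter(rnorm(100), fs, order = 2500),
               "shorter than the filter")
  expect_error(bandpass_filter(rnorm(1000), fs, low_hz = 0), "Band edges")
  expect_error(bandpass_filter(rnorm(1000), fs, high_hz = 300), "Band edges")
  expect_error(bandpass_filter(rnorm(1000)), "`fs_hz` is required")
})

test_that("beat detection recovers rate and period on clean records", {
  rec <- clean_record(ratio_red = 0.2, ratio_inf = 0.2, hr_bpm = 60,
                      duration_s = 12)
  f <- bandpass_filter(rec$red_v, fs, order = 500)
  beats <- detect_beats(f, fs)
  expect_gte(length(attr(beats, "peaks")), 10)
  expect_equal(unique(round(beats$period_s, 2)), 1)
  # tachycardia: 150 bpm -> 0.4 s periods
  rec2 <- clean_record(ratio_red = 0.2, ratio_inf = 0.2, hr_bpm = 150,
                       duration_s = 12)
  beats2 <- detect_beats(bandpass_filter(rec2$red_v, fs, order = 500), fs)
  expect_equal(unique(round(beats2$period_s, 2)), 0.4)
  # beats are half-open, ordered index intervals
  expect_true(all(beats$onset < beats$peak & beats$peak < beats$end))
})

test_that("pure noise yields no stable run and a signal-loss flag", {
  rec <- clean_record(duration_s = 12)
  set.seed(42)
  rec$red_v <- rnorm(length(rec$red_v), 5, 0.5)
  rec$inf_v <- rnorm(length(rec$inf_v), 3, 0.5)
  m <- extract_metrics(rec, order = 500)
  expect_true(m$signal_loss)
  expect_true(is.na(m$ratio_red))
  expect_equal(m$n_beats_used, 0L)
})

test_that("stable-run selection minimises CV and excludes corrupted beats", {
  mk <- function(period, ac) {
    n <- length(period)
    onset <- cumsum(c(1, round(period[-n] * fs)))
    tibble::tibble(onset = as.integer(onset),
                   peak = as.integer(onset + 100),
                   end = as.integer(onset + round(period * fs)),
                   period_s = period, ac_v = ac)
  }
  # 12 identical beats: first window of 9 selected, CVs zero
  b <- mk(rep(1, 12), rep(0.4, 12))
  run <- select_stable_run(b, k = 9)
  expect_true(run$ok)
  expect_equal(run$idx, 1:9)
  expect_equal(run$cv_period, 0)
  expect_equal(run$cv_amp, 0)
  # one corrupted beat in the middle of 20: selected run avoids it
  ac <- rep(0.4, 20); ac[10] <- 2.5
  b2 <- mk(rep(1, 20), ac)
  run2 <- select_stable_run(b2, k = 9)
  expect_true(run2$ok)
  expect_false(10 %in% run2$idx)
  # too few beats for k = 9: signal loss
  run3 <- select_stable_run(mk(rep(1, 5), rep(0.4, 5)), k = 9)
  expect_false(run3$ok)
  expect_error(select_stable_run(b, k = 1), "at least 2")
})

test_that("extracted AC/DC match closed-form values on an analytic waveform", {
  # sinusoid: DC 2 V, peak-to-trough 0.4 V at 2 Hz -> ac 0.4, dc 2, ratio 0.2
  t <- (0:(20 * fs - 1)) / fs
  x <- 2 + 0.2 * sin(2 * pi * 2 * t)
  rec <- structure(list(fs_hz = fs, adc_bits = 16L, adc_range_v = c(0, 20),
                        start_time_s = 0, red_v = x, inf_v = x),
                   class = "waveform_record")
  m <- extract_metrics(rec, hr_range_bpm = c(56, 159))
  expect_false(m$signal_loss)
  expect_equal(m$ac_red_v, 0.4, tolerance = 0.01)
  expect_equal(m$dc_red_v, 2.0, tolerance = 0.001)
  expect_equal(m$ratio_red, 0.2, tolerance = 0.01)
  expect_equal(m$n_beats_used, 9L)
})

test_that("simulator round trip recovers the generating ratios", {
  # noise-free: within the 1% filter-ripple tolerance
  rec <- clean_record(hr_bpm = 72)
  m <- extract_metrics(rec)
  expect_equal(m$ratio_red, 0.0313, tolerance = 0.01)
  expect_equal(m$ratio_inf, 0.0373, tolerance = 0.01)
  # default noise and wander: within 2% relative error
  for (hr in c(60, 95, 140)) {
    rec2 <- waveform_synthesize(0.0313, 0.0373, hr_bpm = hr, duration_s = 20,
                                seed = hr)
    m2 <- extract_metrics(rec2)
    expect_lt(abs(m2$ratio_red / 0.0313 - 1), 0.02)
    expect_lt(abs(m2$ratio_inf / 0.0373 - 1), 0.02)
  }
})

test_that("ratios are gain-equivariant and DC offsets move only DC", {
  rec <- clean_record(hr_bpm = 80)
  m0 <- extract_metrics(rec)
  # common gain on both channels leaves the ratios unchanged
  rec_g <- rec
  rec_g$red_v <- 1.7 * rec$red_v
  rec_g$inf_v <- 1.7 * rec$inf_v
  m_g <- extract_metrics(rec_g)
  expect_equal(m_g$ratio_red, m0$ratio_red, tolerance = 1e-6)
  expect_equal(m_g$ratio_inf, m0$ratio_inf, tolerance = 1e-6)
  expect_equal(m_g$ac_red_v, 1.7 * m0$ac_red_v, tolerance = 1e-6)
  # constant offset changes DC, not AC
  rec_o <- rec
  rec_o$red_v <- rec$red_v + 1.5
  m_o <- extract_metrics(rec_o)
  expect_equal(m_o$ac_red_v, m0$ac_red_v, tolerance = 1e-3)
  expect_equal(m_o$dc_red_v, m0$dc_red_v + 1.5, tolerance = 1e-3)
})
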