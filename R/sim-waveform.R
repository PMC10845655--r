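# Periodic beat template: systolic Gaussian plus a delayed, smaller Gaussian
# that produces the slight dicrotic notch characteristic of descending-aortic
# PPG. Evaluated at fractional phase in [0, 1); neighbouring periods are
# wrapped in so the waveform is smooth across beat boundaries. The template is
# normalised to zero mean and unit peak-to-trough over one period, so a
# channel built as DC * (1 + r * template) has a pulsatile peak-to-trough of
# exactly r * DC.
beat_template_raw <- function(phase) {
  g <- function(x, mu, sig) exp(-0.5 * ((x - mu) / sig)^2)
  val <- 0
  for (shift in -1:1) {
    x <- phase + shift
    val <- val + g(x, 0.30, 0.10) + 0.40 * g(x, 0.62, 0.085)
  }
  val
}

beat_template <- local({
  grid <- seq(0, 1, length.out = 4096 + 1)[-(4096 + 1)]
  raw <- NULL
  function(phase) {
    if (is.null(raw)) raw <<- beat_template_raw(grid)
    m <- mean(raw)
    p2t <- max(raw) - min(raw)
    (beat_template_raw(phase) - m) / p2t
  }
})

#' Synthesize a two-channel dPPG waveform record
#'
#' Builds red and infrared voltage traces as
#' `DC * (1 + r * beat(t)) + wander + artifacts + noise`, where `beat()` is a
#' zero-mean, unit peak-to-trough periodic pulse (systolic peak plus slight
#' dicrotic notch) at the cardiac fundamental `hr_bpm / 60` Hz, `wander` is a
#' low-frequency respiratory baseline oscillation, and optional peristalsis
#' transients are smooth Gaussian bumps. The result is quantised to the
#' recorder's ADC depth over its voltage range.
#'
#' @param ratio_red,ratio_inf Fractional AC/DC ratios in (0, 1); these are the
#'   ground-truth pulsatile fractions of each channel.
#' @param dc_red_v,dc_inf_v DC voltage level per channel (V).
#' @param hr_bpm Heart rate; must lie within `config$hr_range_bpm`.
#' @param duration_s Record length in seconds (at least 3 beat periods).
#' @param config A [sim_config()] supplying `fs_hz`, `adc_bits`,
#'   `adc_range_v` and `hr_range_bpm`.
#' @param wander_frac Amplitude of the respiratory baseline wander as a
#'   fraction of the DC level.
#' @param wander_hz Respiratory wander frequency (Hz, below 0.5).
#' @param noise_sd_v SD of additive white measurement noise (V).
#' @param n_peristalsis Number of peristalsis transients to superimpose.
#' @param peristalsis_amp_v,peristalsis_width_s Amplitude (V) and Gaussian
#'   width (s) of each transient.
#' @param start_time_s Timestamp of the first sample.
#' @param seed Optional integer seed.
#'
#' @return A `waveform_record`: list with `fs_hz`, `adc_bits`, `adc_range_v`,
#'   `start_time_s`, `red_v`, `inf_v` and a `truth` attribute holding the
#'   generating parameters.
#' @examples
#' rec <- waveform_synthesize(0.03, 0.04, hr_bpm = 72, duration_s = 10, seed = 1)
#' rec
#' @export
waveform_synthesize <- function(ratio_red, ratio_inf,
                                dc_red_v = 6.90, dc_inf_v = 3.13,
                                hr_bpm = 95, duration_s = 20,
                                config = sim_config(),
                                wander_frac = 0.01, wander_hz = 0.25,
                                noise_sd_v = 0.002,
                                n_peristalsis = 0,
                                peristalsis_amp_v = 0.3,
                                peristalsis_width_s = 1.5,
                                start_time_s = 0,
                                seed = NULL) {
  stopifnot(inherits(config, "sim_config"))
  for (r in c(ratio_red, ratio_inf)) {
    if (!is.finite(r) || r <= 0 || r >= 1) {
      abort("Ratios must lie strictly between 0 and 1.")
    }
  }
  if (hr_bpm < config$hr_range_bpm[1] || hr_bpm > config$hr_range_bpm[2]) {
    abort(sprintf("`hr_bpm` must lie within the configured range [%g, %g].",
                  config$hr_range_bpm[1], config$hr_range_bpm[2]))
  }
  period <- 60 / hr_bpm
  if (duration_s < 3 * period) {
    abort("`duration_s` must cover at least 3 beat periods; no stable run is possible below that.")
  }
  with_seed(seed, {
    fs <- config$fs_hz
    n <- floor(duration_s * fs)
    t <- (seq_len(n) - 1) / fs
    phase <- (t / period) %% 1
    pulse <- beat_template(phase)

    make_channel <- function(dc, ratio) {
      x <- dc * (1 + ratio * pulse)
      x <- x + dc * wander_frac * sin(2 * pi * wander_hz * t + runif(1, 0, 2 * pi))
      if (n_peristalsis > 0) {
        centers <- runif(n_peristalsis, 0, duration_s)
        for (ct in centers) {
          x <- x + peristalsis_amp_v * exp(-0.5 * ((t - ct) / peristalsis_width_s)^2)
        }
      }
      if (noise_sd_v > 0) x <- x + rnorm(n, 0, noise_sd_v)
      quantize(x, config$adc_bits, config$adc_range_v)
    }

    rec <- structure(
      list(
        fs_hz = fs,
        adc_bits = config$adc_bits,
        adc_range_v = config$adc_range_v,
        start_time_s = start_time_s,
        red_v = make_channel(dc_red_v, ratio_red),
        inf_v = make_channel(dc_inf_v, ratio_inf)
      ),
      class = "waveform_record"
    )
    attr(rec, "truth") <- list(ratio_red = ratio_red, ratio_inf = ratio_inf,
                               dc_red_v = dc_red_v, dc_inf_v = dc_inf_v,
                               hr_bpm = hr_bpm)
    rec
  })
}

quantize <- function(x, bits, range_v) {
  step <- diff(range_v) / (2^bits - 1)
  q <- range_v[1] + step * round((x - range_v[1]) / step)
  pmin(pmax(q, range_v[1]), range_v[2])
}

#' @export
print.waveform_record <- function(x, ...) {
  cat(sprintf("<waveform_record> %d samples x 2 channels @ %g Hz (%.1f s), %d-bit\n",
              length(x$red_v), x$fs_hz, length(x$red_v) / x$fs_hz, x$adc_bits))
  invisible(x)
}

#' @export
as.data.frame.waveform_record <- function(x, ...) {
  data.frame(
    t_s = x$start_time_s + (seq_along(x$red_v) - 1) / x$fs_hz,
    red_v = x$red_v,
    inf_v = x$inf_v
  )
}

#' Write / read the plain-text waveform format
#'
#' Waveform records are exchanged as plain-text files: tab-separated header
#' lines (`fs_hz`, `adc_bits`, `adc_range_v`, `start_time_s`, then a
#' `channels` line naming the columns) followed by one sample per line,
#' `t_s<TAB>red_v<TAB>inf_v`.
#'
#' @param record A `waveform_record`.
#' @param path File path.
#' @return `write_waveform()` returns `path` invisibly; `read_waveform()`
#'   returns a `waveform_record`.
#' @export
write_waveform <- function(record, path) {
  stopifnot(inherits(record, "waveform_record"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("fs_hz\t%.10g", record$fs_hz),
    sprintf("adc_bits\t%d", record$adc_bits),
    sprintf("adc_range_v\t%.10g\t%.10g", record$adc_range_v[1], record$adc_range_v[2]),
    sprintf("start_time_s\t%.10g", record$start_time_s),
    "channels\tt_s\tred_v\tinf_v"
  ), con)
  df <- as.data.frame(record)
  utils::write.table(format(df, digits = 9, scientific = FALSE, trim = TRUE),
                     con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_waveform
#' @export
read_waveform <- function(path) {
  lines <- readLines(path, n = 5L)
  hdr <- strsplit(lines, "\t", fixed = TRUE)
  keys <- vapply(hdr, `[[`, "", 1)
  need <- c("fs_hz", "adc_bits", "adc_range_v", "start_time_s", "channels")
  if (!identical(keys, need)) {
    bad <- which(keys != need)[1]
    abort(sprintf("Malformed waveform header in '%s' at line %d: expected key '%s', found '%s'.",
                  path, bad, need[bad], keys[bad]))
  }
  body <- utils::read.table(path, sep = "\t", skip = 5L,
                            col.names = c("t_s", "red_v", "inf_v"),
                            colClasses = "numeric")
  if (anyNA(body)) {
    bad <- which(apply(is.na(body), 1, any))[1]
    abort(sprintf("Corrupted sample line in '%s' at line %d.", path, bad + 5L))
  }
  structure(
    list(
      fs_hz = as.numeric(hdr[[1]][2]),
      adc_bits = as.integer(hdr[[2]][2]),
      adc_range_v = as.numeric(hdr[[3]][2:3]),
      start_time_s = as.numeric(hdr[[4]][2]),
      red_v = body$red_v,
      inf_v = body$inf_v
    ),
    class = "waveform_record"
  )
}
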