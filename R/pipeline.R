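#' Simulate a study and write waveforms, truth table and manifest
#'
#' Runs [simulate_protocol()], maps each paired sample to ground-truth AC/DC
#' ratios via the optical model, synthesizes a two-channel waveform segment
#' per sample, and writes everything to `out_dir`: one plain-text waveform
#' file per sample, a `samples.csv` index/truth table, and a `manifest.json`
#' recording the configuration, seed, package version, per-stage record
#' counts and every output file.
#'
#' @param config A [sim_config()].
#' @param optical An [optical_model()].
#' @param out_dir Output directory (created if missing).
#' @param seed Integer seed driving the whole run.
#' @param duration_s Length of each waveform segment (s). The study pairing
#'   used 2-minute segments; shorter segments keep desk-scale runs light.
#' @param write_waveforms If `FALSE`, only the truth table and manifest are
#'   written (metric-level simulation).
#' @param ... Passed to [waveform_synthesize()] (e.g. `noise_sd_v`,
#'   `wander_frac`, `n_peristalsis`).
#'
#' @return The manifest (a list), invisibly. The truth table is at
#'   `file.path(out_dir, "samples.csv")`.
#' @export
run_simulate <- function(config = sim_config(), optical = optical_model(),
                         out_dir, seed = 1, duration_s = 20,
                         write_waveforms = TRUE, ...) {
  stopifnot(inherits(config, "sim_config"), inherits(optical, "optical_model"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  t0 <- Sys.time()
  seeds <- child_seeds(seed, 3)
  prot <- simulate_protocol(config, seed = seeds[1])
  ratios <- ratios_from_hb(prot$hb_true_gL, optical, seed = seeds[2])
  samples <- dplyr::bind_cols(prot, ratios[, c("ratio_red", "ratio_inf")])
  # truth columns carry a _true suffix so extracted metrics keep the
  # canonical names when the index is joined back in run_extract()
  samples <- dplyr::rename(samples, ratio_red_true = "ratio_red",
                           ratio_inf_true = "ratio_inf")

  wf_seeds <- child_seeds(seeds[3], nrow(samples) + 2)
  samples$dc_red_true_v <- with_seed(wf_seeds[nrow(samples) + 1],
    rnorm_trunc(nrow(samples), optical$dc_red_v, optical$dc_red_sd_v,
                lower = 0.27, upper = 17.71))
  samples$dc_inf_true_v <- with_seed(wf_seeds[nrow(samples) + 2],
    rnorm_trunc(nrow(samples), optical$dc_inf_v, optical$dc_inf_sd_v,
                lower = 0.05))

  samples$file <- NA_character_
  if (write_waveforms) {
    for (i in seq_len(nrow(samples))) {
      rec <- waveform_synthesize(
        ratio_red = samples$ratio_red_true[i],
        ratio_inf = samples$ratio_inf_true[i],
        dc_red_v = samples$dc_red_true_v[i],
        dc_inf_v = samples$dc_inf_true_v[i],
        hr_bpm = samples$hr_bpm[i], duration_s = duration_s,
        config = config, start_time_s = samples$timestamp_s[i],
        seed = wf_seeds[i], ...
      )
      fn <- sprintf("pig%02d_%s_%02d.txt", samples$pig_id[i],
                    substr(samples$stage[i], 1, 4), samples$step_index[i])
      write_waveform(rec, file.path(out_dir, fn))
      samples$file[i] <- fn
    }
  }
  utils::write.csv(samples, file.path(out_dir, "samples.csv"),
                   row.names = FALSE)

  manifest <- list(
    package = "dppghb",
    version = as.character(utils::packageVersion("dppghb")),
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    seed = seed,
    duration_s = duration_s,
    config = unclass(config),
    optical = unclass(optical),
    counts = list(
      n_pigs = config$n_pigs,
      n_samples = nrow(samples),
      n_waveform_files = sum(!is.na(samples$file)),
      empty_pigs = attr(prot, "empty_pigs")
    ),
    files = c("samples.csv", samples$file[!is.na(samples$file)]),
    elapsed_s = as.numeric(difftime(Sys.time(), t0, units = "secs"))
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  message(sprintf("simulate: %d samples from %d pig(s) -> %s (%.1f s)",
                  nrow(samples), config$n_pigs, out_dir, manifest$elapsed_s))
  invisible(manifest)
}

#' Extract metrics from a directory of waveform files
#'
#' Reads every waveform file written by [run_simulate()] (using the
#' `samples.csv` index when present, otherwise all `*.txt` files) and runs
#' [extract_metrics()] on each. Signal-loss segments are flagged, never
#' dropped.
#'
#' @param waveform_dir Directory containing the waveform files.
#' @param out_csv Optional path for the paired-table CSV.
#' @param ... Extraction parameters passed to [extract_metrics()].
#'
#' @return A tibble with one row per segment: the index columns (pig, stage,
#'   step, reference Hb when available) plus the extracted metrics.
#' @export
run_extract <- function(waveform_dir, out_csv = NULL, ...) {
  if (!dir.exists(waveform_dir)) {
    abort(sprintf("No input: directory '%s' does not exist.", waveform_dir))
  }
  index_path <- file.path(waveform_dir, "samples.csv")
  if (file.exists(index_path)) {
    index <- tibble::as_tibble(utils::read.csv(index_path))
    index <- index[!is.na(index$file), ]
    files <- index$file
  } else {
    files <- list.files(waveform_dir, pattern = "\\.txt$")
    index <- tibble::tibble(file = files)
  }
  if (length(files) == 0) {
    abort(sprintf("No input: no waveform files found in '%s'.", waveform_dir))
  }
  metrics <- purrr::map(files, function(fn) {
    rec <- read_waveform(file.path(waveform_dir, fn))
    extract_metrics(rec, ...)
  })
  out <- dplyr::bind_cols(index, dplyr::bind_rows(metrics))
  n_loss <- sum(out$signal_loss)
  message(sprintf("extract: %d segment(s), %d flagged as signal loss",
                  nrow(out), n_loss))
  if (!is.null(out_csv)) utils::write.csv(out, out_csv, row.names = FALSE)
  out
}

#' Evaluate a paired table and write the report
#'
#' Runs [agreement_report()] on a paired table (or its CSV path) and, when
#' `out_dir` is given, writes `report.json` together with the four
#' publication-style figures (Bland-Altman, ROC, polar trend, error grid).
#'
#' @param data Paired table (data frame) or path to a paired-table CSV.
#' @param model `hb_model` to evaluate, or `NULL` to fit stepwise on the
#'   table itself.
#' @param out_dir Optional output directory.
#' @param ... Passed to [agreement_report()].
#'
#' @return The `agreement_report`, invisibly.
#' @export
run_evaluate <- function(data, model = published_model(), out_dir = NULL,
                         ...) {
  if (is.character(data)) {
    if (!file.exists(data)) abort(sprintf("No such file: '%s'.", data))
    data <- tibble::as_tibble(utils::read.csv(data))
  }
  report <- agreement_report(data, model = model, ...)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_agreement_report(report, file.path(out_dir, "report.json"))
    save_plot <- function(p, fn) {
      suppressMessages(ggplot2::ggsave(file.path(out_dir, fn), p,
                                       width = 6, height = 5, dpi = 150))
    }
    save_plot(plot_bland_altman(report$bland_altman), "bland_altman.png")
    save_plot(plot_polar_trend(report$polar), "polar_trend.png")
    save_plot(plot_error_grid(report$grid), "error_grid.png")
    for (nm in names(report$roc)) {
      save_plot(plot_roc(report$roc[[nm]]), paste0("roc_", nm, ".png"))
    }
  }
  message(sprintf(
    "evaluate: %d pairs; bias %.2f g/L, LOA %.2f to %.2f g/L, PE %.1f%%",
    report$n_pairs, report$bland_altman$bias, report$bland_altman$loa_low,
    report$bland_altman$loa_high, report$bland_altman$percentage_error))
  invisible(report)
}

#' End-to-end desk-scale study replication
#'
#' Chains the whole pipeline at a configurable scale: simulate a
#' hemodilution-transfusion study, optionally pass every sample through
#' waveform synthesis and metric extraction (otherwise use the metric-level
#' ratios directly), fit the stepwise regression, and evaluate the full
#' agreement battery against the reference Hb.
#'
#' @param seed Integer seed for the whole run.
#' @param config A [sim_config()]; the default is the full 19-pig study.
#' @param optical An [optical_model()].
#' @param waveforms If `TRUE`, go through waveform synthesis and signal
#'   processing (slower); if `FALSE` (default), use metric-level ratios.
#' @param duration_s Segment length when `waveforms = TRUE`.
#' @param out_dir Optional directory for waveforms, reports and figures.
#' @param model `"stepwise"` to fit on the simulated data, `"published"` to
#'   evaluate the fixed published model.
#'
#' @return A list: `data` (paired table), `model` (`hb_model`), `report`
#'   (`agreement_report`).
#' @examples
#' \donttest{
#' res <- replicate_study(seed = 1, config = sim_config(n_pigs = 4))
#' res$report$bland_altman
#' }
#' @export
replicate_study <- function(seed = 1, config = sim_config(),
                            optical = optical_model(), waveforms = FALSE,
                            duration_s = 20, out_dir = NULL,
                            model = c("stepwise", "published")) {
  model <- match.arg(model)
  if (waveforms) {
    wdir <- out_dir %||% tempfile("dppg_sim_")
    run_simulate(config, optical, out_dir = wdir, seed = seed,
                 duration_s = duration_s, write_waveforms = TRUE)
    data <- run_extract(wdir)
  } else {
    seeds <- child_seeds(seed, 2)
    prot <- simulate_protocol(config, seed = seeds[1])
    ratios <- ratios_from_hb(prot$hb_true_gL, optical, seed = seeds[2])
    data <- dplyr::bind_cols(prot, ratios[, c("ratio_red", "ratio_inf")])
  }
  fitted <- if (model == "stepwise") fit_stepwise(data) else published_model()
  report <- run_evaluate(data, model = fitted,
                         out_dir = if (!is.null(out_dir)) file.path(out_dir, "report"))
  list(data = data, model = fitted, report = report)
}
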