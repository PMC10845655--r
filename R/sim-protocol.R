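#' Simulate a stepwise hemodilution-transfusion protocol
#'
#' Generates per-animal true and reference Hb trajectories under stepwise
#' isovolemic exchange. Each protocol step withdraws `withdrawal_step_ml` of
#' blood replaced by fluid (plus `fluid_ml_per_step` of additional fluid
#' exchange), so the true Hb follows the single-compartment dilution law
#' `Hb[k+1] = Hb[k] * (1 - V_ex / BV)` with `V_ex` the effective exchange
#' volume and `BV` the animal's blood volume. Dilution continues until the
#' true Hb first falls below `hemodilution_stop_gL`; the stored blood is then
#' reinfused over the same number of steps, retracing the trajectory upward.
#' One paired sample (true Hb, noisy reference Hb, heart rate, timestamp) is
#' emitted after every step.
#'
#' @param config A [sim_config()].
#' @param seed Optional integer overriding `config$seed`.
#'
#' @return A tibble with one row per paired sample: `pig_id`, `weight_kg`,
#'   `stage` (`"hemodilution"` or `"transfusion"`), `step_index` (1-based
#'   within stage), `hb_true_gL`, `hb_ref_gL`, `hr_bpm`, `timestamp_s`.
#'   Animals whose drawn baseline is already below the stop threshold
#'   contribute no rows and are flagged with a warning; their ids are kept in
#'   the `empty_pigs` attribute.
#' @examples
#' prot <- simulate_protocol(sim_config(n_pigs = 2, seed = 7))
#' dplyr::count(prot, pig_id, stage)
#' @export
simulate_protocol <- function(config = sim_config(), seed = NULL) {
  stopifnot(inherits(config, "sim_config"))
  validate_sim_config(config)
  seed <- seed %||% config$seed
  with_seed(seed, {
    pigs <- purrr::map(seq_len(config$n_pigs), function(pid) {
      simulate_one_pig(pid, config)
    })
    empty <- purrr::map_lgl(pigs, ~ nrow(.x) == 0)
    if (any(empty)) {
      warn(sprintf(
        "%d animal(s) had baseline Hb at or below the dilution stop threshold; empty runs flagged (ids: %s).",
        sum(empty), paste(which(empty), collapse = ", ")
      ))
    }
    out <- dplyr::bind_rows(pigs)
    attr(out, "empty_pigs") <- which(empty)
    out
  })
}

simulate_one_pig <- function(pid, config) {
  weight <- rnorm_trunc(1, config$weight_mean_kg, config$weight_sd_kg,
                        lower = 0.5 * config$weight_mean_kg)
  bv <- weight * config$blood_volume_ml_per_kg
  v_ex <- config$withdrawal_step_ml + config$fluid_ml_per_step
  if (v_ex >= bv) {
    abort("Per-step exchange volume reaches the whole blood volume; check the config.")
  }
  frac <- 1 - v_ex / bv
  baseline <- rnorm_trunc(1, config$baseline_hb_mean, config$baseline_hb_sd,
                          lower = 1)
  hr_pig <- rnorm_trunc(1, config$hr_mean_bpm, config$hr_sd_bpm,
                        lower = config$hr_range_bpm[1],
                        upper = config$hr_range_bpm[2])

  if (baseline <= config$hemodilution_stop_gL) {
    return(tibble::tibble(
      pig_id = integer(), weight_kg = numeric(), stage = character(),
      step_index = integer(), hb_true_gL = numeric(), hb_ref_gL = numeric(),
      hr_bpm = numeric(), timestamp_s = numeric()
    ))
  }

  traj <- numeric(0)
  hb <- baseline
  repeat {
    hb <- hb * frac
    traj <- c(traj, hb)
    if (hb < config$hemodilution_stop_gL) break
  }
  k <- length(traj)
  hb_true <- c(traj, rev(traj / frac))  # reinfusion retraces upward to baseline
  stage <- rep(c("hemodilution", "transfusion"), each = k)
  step <- c(seq_len(k), seq_len(k))

  n <- length(hb_true)
  hb_true <- pmax(hb_true + rnorm(n, 0, config$hb_residual_sd_gL), 1)
  hb_ref <- pmax(hb_true + rnorm(n, 0, config$ref_noise_sd_gL), 1)
  hr <- pmin(pmax(hr_pig + rnorm(n, 0, 4),
                  config$hr_range_bpm[1]), config$hr_range_bpm[2])

  tibble::tibble(
    pig_id = pid,
    weight_kg = weight,
    stage = stage,
    step_index = as.integer(step),
    hb_true_gL = hb_true,
    hb_ref_gL = hb_ref,
    hr_bpm = hr,
    timestamp_s = 180 * (seq_len(n) - 1)
  )
}
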