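#' Full method-comparison report for a paired metric table
#'
#' Runs the complete evaluation battery on a paired table of dPPG metrics
#' and reference Hb: Pearson correlations of each AC/DC ratio (and of the
#' model prediction) with the reference; transfusion-trigger ROC analyses at
#' both decision thresholds (reference below the lower trigger, positives
#' scoring low; reference above the upper trigger, positives scoring high);
#' repeated-measures Bland-Altman with percentage error; polar-plot trending
#' concordance; and the three-zone clinical error grid. All configurable
#' constants are echoed in the result.
#'
#' @param data Paired table with columns `ratio_red`, `ratio_inf`,
#'   `hb_ref_gL` and (for repeated-measures components) `pig_id`. Signal-loss
#'   rows (`NA` metrics) are dropped with their count reported.
#' @param model An `hb_model` used to compute `hb_dppg_gL`, or `NULL` to fit
#'   one by [fit_stepwise()] on the same table.
#' @param triggers Length-2 transfusion decision thresholds (g/L).
#' @param exclusion_radius,limit_deg Polar-plot parameters, see
#'   [polar_trend()].
#' @param ci_method AUC CI method, see [roc_analysis()].
#'
#' @return An `agreement_report`: list with `model`, `correlations` (tibble),
#'   `roc` (named list of `roc_result`), `bland_altman`, `polar`, `grid`,
#'   `n_pairs`, `n_signal_loss`, `params`.
#' @examples
#' d <- metric_dataset(200, seed = 3)
#' rep <- agreement_report(d)
#' rep$bland_altman
#' @export
agreement_report <- function(data, model = published_model(),
                             triggers = c(60, 100),
                             exclusion_radius = 2, limit_deg = 30,
                             ci_method = "delong") {
  stop_if_not_df(data, c("ratio_red", "ratio_inf", "hb_ref_gL"))
  data <- tibble::as_tibble(data)
  if (!"pig_id" %in% names(data)) data$pig_id <- 1L
  n_in <- nrow(data)
  data <- data[stats::complete.cases(data[, c("ratio_red", "ratio_inf", "hb_ref_gL")]), ]
  n_loss <- n_in - nrow(data)

  if (is.null(model)) model <- fit_stepwise(data)
  data <- predict_hb(data, model)

  correlations <- dplyr::bind_rows(
    dplyr::mutate(pearson_corr(data, ratio_red, hb_ref_gL), metric = "ratio_red"),
    dplyr::mutate(pearson_corr(data, ratio_inf, hb_ref_gL), metric = "ratio_inf"),
    dplyr::mutate(pearson_corr(data, hb_dppg_gL, hb_ref_gL), metric = "hb_dppg")
  )[, c("metric", "r", "p_value", "n", "conf_low", "conf_high")]

  low <- triggers[1]; high <- triggers[2]
  roc <- list()
  for (sc in c("ratio_red", "ratio_inf")) {
    dlow <- dplyr::mutate(data, .state = .data$hb_ref_gL < low)
    dhigh <- dplyr::mutate(data, .state = .data$hb_ref_gL > high)
    if (length(unique(dlow$.state)) == 2) {
      roc[[paste0(sc, "_low")]] <- roc_analysis(
        dlow, !!rlang::sym(sc), .state,
        direction = "low-positive", ci_method = ci_method)
    }
    if (length(unique(dhigh$.state)) == 2) {
      roc[[paste0(sc, "_high")]] <- roc_analysis(
        dhigh, !!rlang::sym(sc), .state,
        direction = "high-positive", ci_method = ci_method)
    }
  }

  ba <- bland_altman_rm(data, hb_ref_gL, hb_dppg_gL, pig_id)
  polar <- polar_trend(data, hb_ref_gL, hb_dppg_gL, pig_id,
                       exclusion_radius = exclusion_radius,
                       limit_deg = limit_deg)
  grid <- error_grid(data, hb_ref_gL, hb_dppg_gL, thresholds = triggers)

  out <- list(
    model = model,
    correlations = correlations,
    roc = roc,
    bland_altman = ba,
    polar = polar,
    grid = grid,
    n_pairs = nrow(data),
    n_signal_loss = n_loss,
    params = list(triggers = triggers, exclusion_radius = exclusion_radius,
                  limit_deg = limit_deg, ci_method = ci_method)
  )
  class(out) <- "agreement_report"
  out
}

#' @export
print.agreement_report <- function(x, ...) {
  cat(sprintf("<agreement_report> %d pairs (%d signal-loss rows dropped)\n",
              x$n_pairs, x$n_signal_loss))
  cat("Correlations with reference Hb:\n")
  for (i in seq_len(nrow(x$correlations))) {
    cat(sprintf("  %-10s r = %.3f\n", x$correlations$metric[i],
                x$correlations$r[i]))
  }
  for (nm in names(x$roc)) {
    cat(sprintf("ROC %-14s AUC %.2f (%.2f-%.2f), cutoff %.4g\n", nm,
                x$roc[[nm]]$auc, x$roc[[nm]]$auc_ci[1], x$roc[[nm]]$auc_ci[2],
                x$roc[[nm]]$cutoff))
  }
  print(x$bland_altman)
  print(x$polar)
  print(x$grid)
  invisible(x)
}

#' Serialize an agreement report to JSON
#'
#' Writes every numeric result of the report (model, correlations, ROC
#' summaries, Bland-Altman, polar trending, error-grid zones, parameters) as
#' a JSON document; plots never carry numbers that are not also in this
#' report.
#'
#' @param report An `agreement_report`.
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_agreement_report <- function(report, path) {
  stopifnot(inherits(report, "agreement_report"))
  doc <- list(
    model = list(
      predictors = report$model$predictors,
      coefficients = as.list(report$model$coefficients),
      intercept = report$model$intercept,
      source = report$model$source
    ),
    correlations = report$correlations,
    roc = purrr::map(report$roc, ~ as.list(glance(.x))),
    bland_altman = as.list(glance(report$bland_altman)),
    polar = as.list(glance(report$polar)),
    error_grid = list(zones = report$grid$zones,
                      thresholds = report$grid$thresholds),
    n_pairs = report$n_pairs,
    n_signal_loss = report$n_signal_loss,
    params = report$params
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  invisible(path)
}
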