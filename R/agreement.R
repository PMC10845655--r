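#' Pearson correlation between two columns
#'
#' Product-moment correlation with the two-sided p-value from the t
#' transform, as used to relate each dPPG metric to the reference Hb.
#'
#' @param data A data frame.
#' @param x,y Columns (tidy-eval).
#' @return A one-row tibble: `r`, `p_value`, `statistic`, `n`, `conf_low`,
#'   `conf_high`. With zero variance in either column the correlation is
#'   undefined and reported as `NA` with a warning.
#' @examples
#' pearson_corr(data.frame(a = 1:4, b = c(1, 2, 3, 5)), a, b)
#' @export
pearson_corr <- function(data, x, y) {
  xv <- dplyr::pull(data, {{ x }})
  yv <- dplyr::pull(data, {{ y }})
  ok <- stats::complete.cases(xv, yv)
  xv <- xv[ok]; yv <- yv[ok]
  n <- length(xv)
  if (n < 3) abort("Need at least 3 complete pairs for a correlation.")
  if (var(xv) == 0 || var(yv) == 0) {
    warn("Zero variance: the correlation coefficient is undefined.")
    return(tibble::tibble(r = NA_real_, p_value = NA_real_,
                          statistic = NA_real_, n = n,
                          conf_low = NA_real_, conf_high = NA_real_))
  }
  ct <- cor.test(xv, yv, method = "pearson")
  tibble::tibble(
    r = unname(ct$estimate),
    p_value = ct$p.value,
    statistic = unname(ct$statistic),
    n = n,
    conf_low = ct$conf.int[1],
    conf_high = ct$conf.int[2]
  )
}

#' ROC analysis for a transfusion-trigger threshold
#'
#' Builds the ROC curve of a continuous score against a binary state, with
#' the AUC computed by the trapezoidal rule (equivalently the Mann-Whitney
#' statistic, ties counting one half), a DeLong (default) or bootstrap 95%
#' CI, and the Youden-optimal cut-off (maximising sensitivity + specificity
#' - 1; ties resolve toward higher sensitivity).
#'
#' @param data A data frame.
#' @param score Column with the continuous score (tidy-eval).
#' @param state Column with the binary state (logical or 0/1; tidy-eval).
#' @param direction `"low-positive"` if positives have lower scores (e.g. a
#'   falling AC/DC ratio flagging Hb below the transfusion trigger) or
#'   `"high-positive"` for the opposite.
#' @param ci_method `"delong"` (default) or `"bootstrap"`.
#' @param boot_n Bootstrap replicates when `ci_method = "bootstrap"`.
#'
#' @return A `roc_result`: list with `auc`, `auc_ci` (length 2), `cutoff`,
#'   `sensitivity`, `specificity`, `direction`, `n_pos`, `n_neg`, and the
#'   full `curve` tibble. `tidy()` returns the curve, `glance()` the summary
#'   row.
#' @examples
#' d <- data.frame(s = c(1, 2, 3, 4), y = c(1, 1, 0, 0))
#' roc_analysis(d, s, y, direction = "low-positive")$auc
#' @export
roc_analysis <- function(data, score, state,
                         direction = c("low-positive", "high-positive"),
                         ci_method = c("delong", "bootstrap"),
                         boot_n = 2000) {
  direction <- match.arg(direction)
  ci_method <- match.arg(ci_method)
  s <- dplyr::pull(data, {{ score }})
  y <- as.integer(dplyr::pull(data, {{ state }}))
  ok <- stats::complete.cases(s, y)
  s <- s[ok]; y <- y[ok]
  if (length(unique(y)) < 2) {
    abort("Both classes must be present for a ROC analysis.")
  }
  # pROC convention: direction ">" means controls have higher scores than cases
  proc_dir <- if (direction == "low-positive") ">" else "<"
  roc <- pROC::roc(response = y, predictor = s, direction = proc_dir,
                   levels = c(0, 1), quiet = TRUE)
  auc <- as.numeric(pROC::auc(roc))
  ci <- suppressWarnings(
    if (ci_method == "delong") pROC::ci.auc(roc, method = "delong")
    else pROC::ci.auc(roc, method = "bootstrap", boot.n = boot_n,
                      progress = "none")
  )
  co <- pROC::coords(roc, "best", best.method = "youden",
                     ret = c("threshold", "sensitivity", "specificity"),
                     transpose = FALSE)
  co <- co[order(-co$sensitivity), , drop = FALSE][1, ]
  curve <- pROC::coords(roc, "all",
                        ret = c("threshold", "sensitivity", "specificity"),
                        transpose = FALSE)
  out <- list(
    auc = auc,
    auc_ci = c(ci[1], ci[3]),
    ci_method = ci_method,
    cutoff = co$threshold,
    sensitivity = co$sensitivity,
    specificity = co$specificity,
    direction = direction,
    n_pos = sum(y == 1),
    n_neg = sum(y == 0),
    curve = tibble::as_tibble(curve)
  )
  class(out) <- "roc_result"
  out
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("<roc_result> AUC = %.3f (95%% CI %.3f-%.3f, %s), %s\n",
              x$auc, x$auc_ci[1], x$auc_ci[2], x$ci_method, x$direction))
  cat(sprintf("  Youden cutoff = %.4g (sens %.3f, spec %.3f); %d pos / %d neg\n",
              x$cutoff, x$sensitivity, x$specificity, x$n_pos, x$n_neg))
  invisible(x)
}

#' @export
tidy.roc_result <- function(x, ...) x$curve

#' @export
glance.roc_result <- function(x, ...) {
  tibble::tibble(
    auc = x$auc, ci_low = x$auc_ci[1], ci_high = x$auc_ci[2],
    cutoff = x$cutoff, sensitivity = x$sensitivity,
    specificity = x$specificity, n_pos = x$n_pos, n_neg = x$n_neg,
    direction = x$direction
  )
}

#' Bland-Altman agreement with repeated measures per subject
#'
#' Bias is the mean of the test-minus-reference differences. With repeated
#' measurements per subject where the true quantity changes, the SD of the
#' differences is estimated from one-way variance components of the
#' differences on subject (between-subject + within-subject), following
#' Bland & Altman's multiple-measurements method, so subjects contributing
#' many pairs do not understate the between-subject spread. Limits of
#' agreement are `bias +/- 1.96 * sd` and the percentage error is
#' `100 * 1.96 * sd / mean(reference)`.
#'
#' @param data A data frame of paired measurements.
#' @param ref,test Columns with the reference and test method (tidy-eval),
#'   in g/L.
#' @param subject Subject-id column (tidy-eval); omit for a single-subject /
#'   naive analysis.
#' @param adjust `"subjects"` (default, variance components) or `"naive"`
#'   (pooled SD ignoring subjects). With fewer than 2 subjects the naive SD
#'   is used with a warning.
#'
#' @return A `ba_result`: bias, `sd_diff`, `loa_low`, `loa_high`,
#'   `percentage_error`, `n`, `n_subjects`, `var_within`, `var_between`,
#'   `mean_reference`. `tidy()` returns the per-pair means/differences;
#'   `glance()` the scalar summary.
#' @examples
#' d <- difference_dataset(1.69, 14.13, n = 376, seed = 1)
#' bland_altman_rm(d, hb_ref_gL, hb_test_gL, pig_id)
#' @export
bland_altman_rm <- function(data, ref, test, subject = NULL,
                            adjust = c("subjects", "naive")) {
  adjust <- match.arg(adjust)
  r <- dplyr::pull(data, {{ ref }})
  t <- dplyr::pull(data, {{ test }})
  subj_quo <- enquo(subject)
  subj <- if (rlang::quo_is_null(subj_quo)) rep(1L, length(r))
          else dplyr::pull(data, !!subj_quo)
  ok <- stats::complete.cases(r, t, subj)
  r <- r[ok]; t <- t[ok]; subj <- as.factor(subj[ok])
  n <- length(r)
  if (n < 2) abort("Need at least 2 pairs.")
  d <- t - r
  bias <- mean(d)
  k <- nlevels(droplevels(subj))

  if (adjust == "subjects" && k < 2) {
    warn("Only one subject: falling back to the naive SD of differences.")
    adjust <- "naive"
  }
  if (adjust == "naive") {
    sd_d <- stats::sd(d)
    var_w <- sd_d^2
    var_b <- 0
  } else {
    subj <- droplevels(subj)
    a <- anova(lm(d ~ subj))
    msb <- a$`Mean Sq`[1]
    msw <- a$`Mean Sq`[2]
    ni <- as.numeric(table(subj))
    m0 <- (n - sum(ni^2) / n) / (k - 1)
    var_b <- max(0, (msb - msw) / m0)
    var_w <- msw
    sd_d <- sqrt(var_b + var_w)
  }
  mean_ref <- mean(r)
  out <- list(
    bias = bias,
    sd_diff = sd_d,
    loa_low = bias - 1.96 * sd_d,
    loa_high = bias + 1.96 * sd_d,
    percentage_error = if (mean_ref > 0) percentage_error(sd_d, mean_ref)
                       else NA_real_,
    n = n,
    n_subjects = k,
    var_within = var_w,
    var_between = var_b,
    mean_reference = mean_ref,
    adjust = adjust,
    pairs = tibble::tibble(subject = subj, mean = (r + t) / 2, diff = d)
  )
  class(out) <- "ba_result"
  out
}

#' @export
print.ba_result <- function(x, ...) {
  cat(sprintf("<ba_result> bias %.2f g/L (precision %.2f g/L), LOA %.2f to %.2f g/L\n",
              x$bias, x$sd_diff, x$loa_low, x$loa_high))
  cat(sprintf("  percentage error %.1f%%; n = %d pairs, %d subject(s), %s SD\n",
              x$percentage_error, x$n, x$n_subjects, x$adjust))
  invisible(x)
}

#' @export
tidy.ba_result <- function(x, ...) x$pairs

#' @export
glance.ba_result <- function(x, ...) {
  tibble::tibble(
    bias = x$bias, sd_diff = x$sd_diff,
    loa_low = x$loa_low, loa_high = x$loa_high,
    percentage_error = x$percentage_error,
    n = x$n, n_subjects = x$n_subjects,
    var_within = x$var_within, var_between = x$var_between,
    mean_reference = x$mean_reference
  )
}

#' Percentage error of a test method against a reference
#'
#' `100 * 1.96 * sd_diff / mean_reference`: the 95% span of the differences
#' relative to the mean reference level.
#'
#' @param sd_diff SD of the between-method differences (g/L).
#' @param mean_reference Mean of the reference method (g/L, positive).
#' @return Percentage error (%).
#' @examples
#' percentage_error(14.13, 83.78)
#' @export
percentage_error <- function(sd_diff, mean_reference) {
  if (mean_reference <= 0) abort("`mean_reference` must be positive.")
  100 * 1.96 * sd_diff / mean_reference
}

#' Polar-plot trending concordance
#'
#' Evaluates whether the test method follows within-subject changes of the
#' reference. For each pair of consecutive paired samples within a subject,
#' the change vector (delta-reference, delta-test) is mapped to a polar
#' angle relative to the identity (45 degree) direction,
#' `angle = 45 - atan2(delta_test, delta_ref)` folded into (-90, 90], and a
#' radius `(delta_ref + delta_test) / 2` (g/L). Points with
#' `|radius| < exclusion_radius` are excluded as clinically trivial changes;
#' the concordance rate is the percentage of remaining points with
#' `|angle| <= limit_deg`.
#'
#' @param data A data frame ordered chronologically within subject.
#' @param ref,test Measurement columns (tidy-eval), g/L.
#' @param subject Subject-id column (tidy-eval); consecutive deltas never
#'   cross subjects.
#' @param exclusion_radius Minimum |mean change| (g/L) for a point to count.
#'   The default (2 g/L, the reference analyser's noise scale) drops only
#'   changes indistinguishable from measurement noise; per-step protocol
#'   changes (~3 g/L) remain in the denominator.
#' @param limit_deg Concordance half-angle (degrees).
#'
#' @return A `polar_result`: `points` tibble (`subject`, `delta_ref`,
#'   `delta_test`, `radius`, `angle_deg`, `excluded`), `concordance_rate`
#'   (%), `n_used`, `n_excluded`, and the parameters. If every point is
#'   excluded the rate is `NA` with a warning.
#' @examples
#' d <- difference_dataset(0, 5, n = 40, seed = 2)
#' polar_trend(d, hb_ref_gL, hb_test_gL, pig_id)
#' @export
polar_trend <- function(data, ref, test, subject = NULL,
                        exclusion_radius = 2, limit_deg = 30) {
  r <- dplyr::pull(data, {{ ref }})
  t <- dplyr::pull(data, {{ test }})
  subj_quo <- enquo(subject)
  subj <- if (rlang::quo_is_null(subj_quo)) rep(1L, length(r))
          else dplyr::pull(data, !!subj_quo)
  df <- tibble::tibble(subject = subj, ref = r, test = t)
  pts <- df |>
    dplyr::group_by(.data$subject) |>
    dplyr::reframe(
      delta_ref = diff(.data$ref),
      delta_test = diff(.data$test)
    ) |>
    dplyr::mutate(
      radius = (.data$delta_ref + .data$delta_test) / 2,
      angle_deg = fold_half_circle(
        45 - atan2(.data$delta_test, .data$delta_ref) * 180 / pi),
      excluded = abs(.data$radius) < exclusion_radius
    )
  used <- pts[!pts$excluded, ]
  if (nrow(used) == 0) {
    warn("All change points fall inside the exclusion radius; concordance is undefined.")
    rate <- NA_real_
  } else {
    rate <- 100 * mean(abs(used$angle_deg) <= limit_deg)
  }
  out <- list(
    points = pts,
    concordance_rate = rate,
    n_used = nrow(used),
    n_excluded = sum(pts$excluded),
    exclusion_radius = exclusion_radius,
    limit_deg = limit_deg
  )
  class(out) <- "polar_result"
  out
}

# fold an angle (degrees) into the half circle (-90, 90]
fold_half_circle <- function(a) {
  a <- ((a + 90) %% 180) - 90     # -> [-90, 90)
  ifelse(a == -90, 90, a)
}

#' @export
print.polar_result <- function(x, ...) {
  cat(sprintf("<polar_result> concordance %.1f%% within +/-%g deg (%d used, %d excluded at radius < %g g/L)\n",
              x$concordance_rate, x$limit_deg, x$n_used, x$n_excluded,
              x$exclusion_radius))
  invisible(x)
}

#' @export
tidy.polar_result <- function(x, ...) x$points

#' @export
glance.polar_result <- function(x, ...) {
  tibble::tibble(
    concordance_rate = x$concordance_rate,
    n_used = x$n_used, n_excluded = x$n_excluded,
    exclusion_radius = x$exclusion_radius, limit_deg = x$limit_deg
  )
}

#' Three-zone clinical error grid for Hb measurements
#'
#' Classifies each paired measurement by the clinical consequence of their
#' disagreement, using the transfusion decision bands: L below the lower
#' threshold (transfuse), M between the thresholds (clinical judgement), H
#' above the upper threshold (no transfusion). Zone A: both methods in the
#' same band (no impact); Zone C: one method in L and the other in H
#' (opposite transfusion decisions, an erroneous treatment); Zone B: any
#' other disagreement (minor impact). The band encoding approximates the
#' published three-zone grid polygons by its decision thresholds.
#'
#' @param data A data frame of paired measurements.
#' @param ref,test Measurement columns (tidy-eval), positive, g/L.
#' @param thresholds Length-2 increasing numeric, the transfusion decision
#'   bounds (defaults 60 and 100 g/L).
#'
#' @return An `error_grid_result`: `pairs` tibble with `band_ref`,
#'   `band_test`, `zone`; `zones` tibble with counts and percentages for A,
#'   B, C; `thresholds`.
#' @examples
#' d <- data.frame(ref = c(80, 55, 65), test = c(80, 105, 95))
#' error_grid(d, ref, test)$zones
#' @export
error_grid <- function(data, ref, test, thresholds = c(60, 100)) {
  stopifnot(length(thresholds) == 2, diff(thresholds) > 0)
  r <- dplyr::pull(data, {{ ref }})
  t <- dplyr::pull(data, {{ test }})
  if (any(c(r, t) <= 0, na.rm = TRUE)) abort("Hb values must be positive.")
  band <- function(x) {
    cut(x, breaks = c(-Inf, thresholds[1] - 1e-12, thresholds[2], Inf),
        labels = c("L", "M", "H"))
  }
  br <- band(r); bt <- band(t)
  zone <- dplyr::case_when(
    br == bt ~ "A",
    (br == "L" & bt == "H") | (br == "H" & bt == "L") ~ "C",
    .default = "B"
  )
  n_pairs <- length(zone)
  zones <- tibble::tibble(zone = c("A", "B", "C")) |>
    dplyr::left_join(
      tibble::tibble(zone = zone) |> dplyr::count(.data$zone),
      by = "zone") |>
    dplyr::mutate(
      n = dplyr::coalesce(.data$n, 0L),
      pct = 100 * .data$n / n_pairs
    )
  out <- list(
    pairs = tibble::tibble(ref = r, test = t, band_ref = br,
                           band_test = bt, zone = zone),
    zones = zones,
    thresholds = thresholds
  )
  class(out) <- "error_grid_result"
  out
}

#' @export
print.error_grid_result <- function(x, ...) {
  z <- x$zones
  cat(sprintf("<error_grid_result> A %.0f%% (%d), B %.0f%% (%d), C %.0f%% (%d); bands at %g / %g g/L\n",
              z$pct[1], z$n[1], z$pct[2], z$n[2], z$pct[3], z$n[3],
              x$thresholds[1], x$thresholds[2]))
  invisible(x)
}

#' @export
tidy.error_grid_result <- function(x, ...) x$pairs

#' @export
glance.error_grid_result <- function(x, ...) {
  tidyr::pivot_wider(x$zones, names_from = "zone",
                     values_from = c("n", "pct"))
}

#' Sample-size planning for limits of agreement
#'
#' Standard error of the 95% limits of agreement for a planned method-
#' comparison study: `se_loa = sqrt(3 * s^2 / n)`, where `s` is the expected
#' SD of the between-method differences and `n` the number of measurements;
#' the 95% CI half-width of a limit is `1.96 * se_loa`.
#'
#' @param s Expected SD of differences (g/L), positive.
#' @param n Planned number of measurements (at least 2).
#' @return A one-row tibble: `s`, `n`, `se_loa`, `ci95_halfwidth` (g/L).
#' @examples
#' loa_sample_size(s = 20, n = 300)
#' @export
loa_sample_size <- function(s, n) {
  if (s <= 0) abort("`s` must be positive.")
  if (n < 2) abort("`n` must be at least 2.")
  se <- sqrt(3 * s^2 / n)
  tibble::tibble(s = s, n = n, se_loa = se, ci95_halfwidth = 1.96 * se)
}
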