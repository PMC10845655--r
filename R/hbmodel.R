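new_hb_model <- function(coefficients, intercept, source,
                         r_squared = NA_real_, sigma = NA_real_,
                         n = NA_integer_, steps = NULL, fit = NULL) {
  structure(
    list(
      predictors = names(coefficients),
      coefficients = coefficients,
      intercept = intercept,
      r_squared = r_squared,
      sigma = sigma,
      n = n,
      source = source,
      steps = steps,
      fit = fit
    ),
    class = "hb_model"
  )
}

#' The fixed published two-wavelength Hb model
#'
#' Returns the frozen regression published for descending-aortic PPG:
#' `Hb = 341.84 * ratio_red + 569.61 * ratio_inf + 49.87` (g/L), with both
#' AC/DC ratios as dimensionless fractions.
#'
#' @return An immutable `hb_model`.
#' @examples
#' m <- published_model()
#' predict(m, tibble::tibble(ratio_red = 0, ratio_inf = 0))  # 49.87
#' @export
published_model <- function() {
  new_hb_model(
    coefficients = c(ratio_red = PUB_COEF_RED, ratio_inf = PUB_COEF_INF),
    intercept = PUB_INTERCEPT,
    source = "published"
  )
}

#' Stepwise multiple linear regression of reference Hb on dPPG ratios
#'
#' Forward stepwise ordinary least squares with backward removal: at each
#' step the candidate whose partial t-test p-value (when added to the
#' current model) is smallest enters if below `p_enter`; after every entry,
#' retained predictors whose p-value exceeds `p_remove` are dropped. The
#' default thresholds (0.05 enter, 0.10 remove) follow common statistical
#' package practice. Perfectly collinear candidates are skipped with a
#' warning.
#'
#' @param data A data frame containing the response and candidate columns.
#' @param response Name of the response column (reference Hb, g/L).
#' @param candidates Character vector of candidate predictor columns.
#' @param p_enter,p_remove Entry / removal p-value thresholds
#'   (`p_remove >= p_enter`).
#'
#' @return An `hb_model` with coefficients, intercept, fit diagnostics
#'   (R-squared, residual SD, n), the step log, and the underlying [lm()]
#'   fit. [tidy()] and [glance()] methods are provided.
#' @examples
#' d <- metric_dataset(376, seed = 1)
#' fit_stepwise(d)
#' @export
fit_stepwise <- function(data, response = "hb_ref_gL",
                         candidates = c("ratio_red", "ratio_inf"),
                         p_enter = 0.05, p_remove = 0.10) {
  stop_if_not_df(data, c(response, candidates))
  if (p_remove < p_enter) abort("`p_remove` must be at least `p_enter`.")
  n <- nrow(data)
  if (n <= length(candidates) + 1) {
    abort("Need more rows than candidates + 1 to fit the model.")
  }
  for (cand in candidates) {
    if (var(data[[cand]]) == 0) {
      abort(sprintf("Candidate `%s` is constant; cannot enter a regression.", cand))
    }
  }

  current <- character()
  steps <- character()
  repeat {
    changed <- FALSE
    pool <- setdiff(candidates, current)
    if (length(pool) > 0) {
      pvals <- vapply(pool, function(cand) {
        fit <- ols_fit(data, response, c(current, cand))
        p <- coef_pvalue(fit, cand)
        if (is.na(p)) {
          warn(sprintf("Candidate `%s` is collinear with the current model; skipped.", cand))
          return(Inf)
        }
        p
      }, numeric(1))
      if (min(pvals) < p_enter) {
        add <- pool[which.min(pvals)]
        current <- c(current, add)
        steps <- c(steps, sprintf("enter %s (p = %.3g)", add, min(pvals)))
        changed <- TRUE
      }
    }
    if (length(current) > 1) {
      fit <- ols_fit(data, response, current)
      pv <- vapply(current, function(tm) coef_pvalue(fit, tm), numeric(1))
      worst <- which.max(pv)
      if (pv[worst] > p_remove) {
        steps <- c(steps, sprintf("remove %s (p = %.3g)", current[worst], pv[worst]))
        current <- current[-worst]
        changed <- TRUE
      }
    }
    if (!changed) break
  }

  fit <- ols_fit(data, response, current)
  cf <- coef(fit)
  coefs <- if (length(current) > 0) cf[current] else setNames(numeric(0), character(0))
  s <- summary(fit)
  new_hb_model(
    coefficients = coefs,
    intercept = unname(cf["(Intercept)"]),
    source = "stepwise",
    r_squared = if (length(current) > 0) s$r.squared else 0,
    sigma = s$sigma,
    n = n,
    steps = steps,
    fit = fit
  )
}

ols_fit <- function(data, response, terms) {
  rhs <- if (length(terms) == 0) "1" else paste(terms, collapse = " + ")
  f <- stats::as.formula(paste(response, "~", rhs))
  lm(f, data = data)
}

# p-value of one coefficient; exact-fit models (sigma ~ 0) get p = 0 for any
# non-zero estimate so a perfectly explanatory predictor still enters.
coef_pvalue <- function(fit, term) {
  cf <- summary(fit)$coefficients
  if (!(term %in% rownames(cf))) return(NA_real_)
  est <- cf[term, "Estimate"]
  se <- cf[term, "Std. Error"]
  if (!is.finite(se) || se == 0) return(if (abs(est) > 0) 0 else NA_real_)
  p <- cf[term, "Pr(>|t|)"]
  if (is.nan(p)) p <- if (abs(est) > 1e-12) 0 else 1
  p
}

#' Predict Hb from dPPG metrics
#'
#' `predict()` on an `hb_model` evaluates the affine model on a data frame of
#' metrics and returns a numeric vector (g/L); `predict_hb()` is the
#' pipe-friendly variant that appends the prediction as a column. Rows with
#' missing predictors (e.g. signal-loss segments) propagate `NA`.
#'
#' @param object,model An `hb_model`.
#' @param newdata,data A data frame containing the model's predictor columns.
#' @param col Name of the output column for `predict_hb()`.
#' @param ... Unused.
#' @return `predict()`: numeric vector of Hb (g/L); `predict_hb()`: `data`
#'   with the prediction column appended.
#' @examples
#' predict(published_model(),
#'         tibble::tibble(ratio_red = 0.0313, ratio_inf = 0.0373))
#' @export
predict.hb_model <- function(object, newdata, ...) {
  stop_if_not_df(newdata, object$predictors, "newdata")
  out <- rep(object$intercept, nrow(newdata))
  for (tm in object$predictors) {
    out <- out + object$coefficients[[tm]] * newdata[[tm]]
  }
  unname(out)
}

#' @rdname predict.hb_model
#' @export
predict_hb <- function(data, model = published_model(), col = "hb_dppg_gL") {
  data <- tibble::as_tibble(data)
  data[[col]] <- predict(model, data)
  data
}

#' @export
print.hb_model <- function(x, ...) {
  cat(sprintf("<hb_model> (%s)\n", x$source))
  terms <- paste(sprintf("%.4g * %s", x$coefficients, x$predictors),
                 collapse = " + ")
  if (length(x$predictors) == 0) terms <- "(intercept only)"
  cat(sprintf("  Hb = %s + %.4g  [g/L]\n", terms, x$intercept))
  if (!is.na(x$r_squared)) {
    cat(sprintf("  R^2 = %.4f, residual SD = %.3f g/L, n = %d\n",
                x$r_squared, x$sigma, x$n))
  }
  invisible(x)
}

#' @export
tidy.hb_model <- function(x, ...) {
  if (!is.null(x$fit)) {
    cf <- summary(x$fit)$coefficients
    tibble::tibble(
      term = rownames(cf),
      estimate = cf[, "Estimate"],
      std.error = cf[, "Std. Error"],
      statistic = cf[, "t value"],
      p.value = cf[, "Pr(>|t|)"]
    )
  } else {
    tibble::tibble(
      term = c("(Intercept)", x$predictors),
      estimate = c(x$intercept, unname(x$coefficients)),
      std.error = NA_real_, statistic = NA_real_, p.value = NA_real_
    )
  }
}

#' @export
glance.hb_model <- function(x, ...) {
  tibble::tibble(
    r.squared = x$r_squared,
    sigma = x$sigma,
    nobs = x$n,
    n_predictors = length(x$predictors),
    source = x$source
  )
}

#' Serialize an Hb model to / from JSON
#'
#' Writes the predictor set, coefficients, intercept and diagnostics as a
#' small JSON document (the fitted `lm` object is not serialized).
#'
#' @param model An `hb_model`.
#' @param path File path.
#' @return `write_hb_model()` returns `path` invisibly; `read_hb_model()`
#'   returns an `hb_model`.
#' @export
write_hb_model <- function(model, path) {
  stopifnot(inherits(model, "hb_model"))
  doc <- list(
    predictors = model$predictors,
    coefficients = as.list(model$coefficients),
    intercept = model$intercept,
    r_squared = model$r_squared,
    sigma = model$sigma,
    n = model$n,
    source = model$source
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_hb_model
#' @export
read_hb_model <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  new_hb_model(
    coefficients = unlist(doc$coefficients) %||% setNames(numeric(0), character(0)),
    intercept = doc$intercept,
    source = doc$source %||% "deserialized",
    r_squared = doc$r_squared %||% NA_real_,
    sigma = doc$sigma %||% NA_real_,
    n = doc$n %||% NA_integer_
  )
}
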