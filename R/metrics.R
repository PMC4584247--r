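# Model evaluation: R/RMSE, leave-one-out CV, report assembly.

#' Correlation and root-mean-square error
#'
#' @param y_true,y_pred numeric vectors of equal length (>= 2); `y_true`
#'   must be non-constant for R.
#' @return named numeric vector `c(R = ..., RMSE = ...)`: Pearson
#'   correlation and `sqrt(mean((y_true - y_pred)^2))` (degrees Brix).
#' @examples
#' compute_metrics(c(1, 2, 3), c(2, 2, 2))
#' @export
compute_metrics <- function(y_true, y_pred) {
  if (length(y_true) != length(y_pred) || length(y_true) < 2) {
    stop_invalid("`y_true` and `y_pred` must share a length >= 2")
  }
  if (stats::var(y_true) == 0) {
    stop("R undefined: `y_true` is constant", call. = FALSE)
  }
  r <- if (stats::var(y_pred) == 0) 0 else stats::cor(y_true, y_pred)
  c(R = r, RMSE = sqrt(mean((y_true - y_pred)^2)))
}

#' Relative change between two statistics, in percent
#'
#' `100 * (new - reference) / reference`, sign preserved, reported to
#' 3 significant figures (the precision used when comparing model
#' variants, e.g. the drop in prediction R or the rise in prediction RMSE
#' after reducing the wavelength set).
#'
#' @param reference baseline statistic (nonzero).
#' @param new comparison statistic.
#' @return percent change, rounded to 3 significant figures.
#' @examples
#' relative_change(0.956, 0.925) # -3.24
#' relative_change(0.430, 0.557) # +29.5
#' relative_change(460, 23)      # -95.0
#' @export
relative_change <- function(reference, new) {
  if (any(reference == 0)) stop_invalid("`reference` must be nonzero")
  signif(100 * (new - reference) / reference, 3)
}

#' Leave-one-out cross-validation of a fitting recipe
#'
#' Performs exactly `n` fits, each on `n - 1` samples, predicting the
#' held-out sample; metrics are computed from the `n` held-out
#' predictions.
#'
#' @param X,y training data (`n >= 3` samples).
#' @param model_factory function `(X, y) -> model`; the model must be
#'   usable with [predict()] (or itself be a prediction function
#'   `(newdata) -> numeric`).
#' @return list with `r_cv`, `rmse_cv` and `predictions` (the n held-out
#'   predictions in sample order).
#' @export
loo_cv <- function(X, y, model_factory) {
  X <- as.matrix(X); y <- as.numeric(y)
  n <- nrow(X)
  if (n < 3) stop_invalid("leave-one-out CV needs n >= 3")
  preds <- vapply(seq_len(n), function(i) {
    m <- tryCatch(model_factory(X[-i, , drop = FALSE], y[-i]),
                  error = function(e) {
                    stop(sprintf("fold %d: %s", i, conditionMessage(e)),
                         call. = FALSE)
                  })
    out <- if (is.function(m)) m(X[i, , drop = FALSE])
           else predict(m, X[i, , drop = FALSE])
    as.numeric(out)[1]
  }, numeric(1))
  m <- compute_metrics(y, preds)
  list(r_cv = unname(m["R"]), rmse_cv = unname(m["RMSE"]), predictions = preds)
}

#' Assemble a calibration/cross-validation/prediction metrics report
#'
#' The standard model-comparison row: R and RMSE on the calibration set,
#' under cross-validation, and on the held-out prediction set.
#'
#' @param model a fitted model with a [predict()] method.
#' @param cal_X,cal_y calibration data the model was trained on.
#' @param pred_X,pred_y held-out prediction data.
#' @param cv_predictions optional vector of cross-validated predictions
#'   for the calibration samples (e.g. from [loo_cv()] or
#'   [select_plsr_lv()]); if NULL the CV columns are NA.
#' @return an object of class `metrics_report`: named list with `r_c`,
#'   `rmse_c`, `r_cv`, `rmse_cv`, `r_p`, `rmse_p`.
#' @export
metrics_report <- function(model, cal_X, cal_y, pred_X, pred_y,
                           cv_predictions = NULL) {
  cal <- compute_metrics(cal_y, predict(model, cal_X))
  prd <- compute_metrics(pred_y, predict(model, pred_X))
  cv <- if (is.null(cv_predictions)) c(R = NA_real_, RMSE = NA_real_)
        else compute_metrics(cal_y, cv_predictions)
  structure(list(r_c = unname(cal["R"]), rmse_c = unname(cal["RMSE"]),
                 r_cv = unname(cv["R"]), rmse_cv = unname(cv["RMSE"]),
                 r_p = unname(prd["R"]), rmse_p = unname(prd["RMSE"])),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("  calibration:      R = %6.4f  RMSE = %6.4f\n", x$r_c, x$rmse_c))
  if (!is.na(x$r_cv)) {
    cat(sprintf("  cross-validation: R = %6.4f  RMSE = %6.4f\n", x$r_cv, x$rmse_cv))
  }
  cat(sprintf("  prediction:       R = %6.4f  RMSE = %6.4f\n", x$r_p, x$rmse_p))
  invisible(x)
}

#' @export
as.data.frame.metrics_report <- function(x, ...) {
  data.frame(r_c = x$r_c, rmse_c = x$rmse_c, r_cv = x$r_cv,
             rmse_cv = x$rmse_cv, r_p = x$r_p, rmse_p = x$rmse_p)
}
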