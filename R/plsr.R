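# Partial least squares regression, univariate response (PLS1, NIPALS).
#
# The decomposition X = T P' + E, y = U q' + f with the inner relation
# U = B T is computed component-wise: each weight vector maximizes
# covariance between the X-scores and the current y residual; X and y are
# deflated after every component. Mean-centering only, no variance scaling
# (reflectance bands share units). The model collapses to one regression
# vector per component count:
#   B_k = W_k (P_k' W_k)^{-1} q_{1:k},  intercept = mean(y) - mean(X) B_k.

#' Fit a PLS1 regression model
#'
#' @param X numeric samples x bands matrix.
#' @param y numeric response (degrees Brix), non-constant.
#' @param n_lv number of latent variables,
#'   `1 <= n_lv <= min(nrow(X) - 1, ncol(X))`.
#' @param wavelengths optional band-centre wavelengths (nm) carried on the
#'   model for band lookup during mapping.
#' @return an object of class `plsr_model`: regression `coefficients` (one
#'   per band), `intercept`, the per-component coefficient path
#'   (`coef_path`, bands x n_lv, and `intercept_path`), scores/loadings,
#'   centring means, `fitted` values and `residuals`. Fewer than `n_lv`
#'   components are returned if NIPALS exhausts the X residual first.
#' @examples
#' X <- matrix(rnorm(40), 8, 5)
#' y <- X %*% rnorm(5) + rnorm(8, sd = 0.01)
#' m <- fit_plsr(X, y, n_lv = 3)
#' coef(m)[1:3]
#' @export
fit_plsr <- function(X, y, n_lv, wavelengths = NULL) {
  X <- as.matrix(X); y <- as.numeric(y)
  n <- nrow(X); p <- ncol(X)
  if (length(y) != n) stop_invalid("nrow(X) != length(y)")
  if (stats::var(y) == 0) {
    stop("degenerate response: y has zero variance", call. = FALSE)
  }
  lv_cap <- min(n - 1L, p)
  if (n_lv < 1 || n_lv > lv_cap) {
    stop_invalid("`n_lv` must be in [1, %d]", lv_cap)
  }
  x_mean <- colMeans(X); y_mean <- mean(y)
  Xc <- sweep(X, 2, x_mean)
  yc <- y - y_mean

  W <- matrix(0, p, n_lv); P <- matrix(0, p, n_lv)
  Tm <- matrix(0, n, n_lv); q <- numeric(n_lv)
  k_eff <- 0L
  tol <- 1e-12 * max(1, sum(Xc^2))
  for (k in seq_len(n_lv)) {
    w <- crossprod(Xc, yc)
    wn <- sqrt(sum(w^2))
    if (wn^2 <= tol) break
    w <- w / wn
    tk <- Xc %*% w
    tt <- sum(tk^2)
    if (tt <= tol) break
    pk <- crossprod(Xc, tk) / tt
    qk <- sum(yc * tk) / tt
    Xc <- Xc - tcrossprod(tk, pk)
    yc <- yc - qk * tk
    W[, k] <- w; P[, k] <- pk; Tm[, k] <- tk; q[k] <- qk
    k_eff <- k
  }
  if (k_eff == 0L) {
    stop("degenerate predictors: X has no covariance with y", call. = FALSE)
  }
  W <- W[, seq_len(k_eff), drop = FALSE]
  P <- P[, seq_len(k_eff), drop = FALSE]
  Tm <- Tm[, seq_len(k_eff), drop = FALSE]
  q <- q[seq_len(k_eff)]

  # R = W (P'W)^{-1}: columns give the coefficient increments; the k-LV
  # regression vector is R[, 1:k] %*% q[1:k]
  R <- W %*% solve(crossprod(P, W))
  coef_path <- sapply(seq_len(k_eff), function(k) {
    R[, seq_len(k), drop = FALSE] %*% q[seq_len(k)]
  })
  coef_path <- matrix(coef_path, nrow = p)
  intercept_path <- y_mean - as.numeric(x_mean %*% coef_path)

  beta <- coef_path[, k_eff]
  intercept <- intercept_path[k_eff]
  fitted <- as.numeric(X %*% beta + intercept)
  structure(list(
    n_lv = k_eff, n_lv_requested = as.integer(n_lv),
    coefficients = beta, intercept = intercept,
    coef_path = coef_path, intercept_path = intercept_path,
    weights = W, loadings = P, scores = Tm, y_loadings = q,
    x_mean = x_mean, y_mean = y_mean,
    wavelengths = wavelengths,
    fitted = fitted, residuals = y - fitted
  ), class = "plsr_model")
}

#' @export
coef.plsr_model <- function(object, ...) {
  c(`(Intercept)` = object$intercept, object$coefficients)
}

#' Predict from a PLS1 model
#'
#' @param object a [fit_plsr()] model.
#' @param newdata samples x bands matrix (bands as in training).
#' @param n_lv number of components to use (default: all fitted).
#' @param ... unused.
#' @return numeric vector of predictions (degrees Brix).
#' @export
predict.plsr_model <- function(object, newdata, n_lv = object$n_lv, ...) {
  newdata <- if (is.null(dim(newdata))) matrix(newdata, nrow = 1) else as.matrix(newdata)
  if (ncol(newdata) != length(object$coefficients)) {
    stop_invalid("newdata has %d bands, model expects %d",
                 ncol(newdata), length(object$coefficients))
  }
  if (n_lv < 1 || n_lv > object$n_lv) stop_invalid("`n_lv` out of range")
  as.numeric(newdata %*% object$coef_path[, n_lv] + object$intercept_path[n_lv])
}

#' @export
residuals.plsr_model <- function(object, ...) object$residuals

#' @export
fitted.plsr_model <- function(object, ...) object$fitted

#' @export
print.plsr_model <- function(x, ...) {
  cat(sprintf("<plsr_model> %d latent variables, %d bands\n",
              x$n_lv, length(x$coefficients)))
  cat(sprintf("  training RMSE: %.4f\n", sqrt(mean(x$residuals^2))))
  invisible(x)
}

#' @export
summary.plsr_model <- function(object, ...) {
  y <- object$fitted + object$residuals
  m <- compute_metrics(y, object$fitted)
  cat(sprintf("PLS1 model: %d latent variables, %d bands\n",
              object$n_lv, length(object$coefficients)))
  cat(sprintf("  calibration R = %.4f, RMSE = %.4f\n", m[["R"]], m[["RMSE"]]))
  invisible(object)
}

#' Choose the PLS component count by cross-validated RMSE
#'
#' Leave-one-out (or k-fold) cross-validation over `1..lv_max` components;
#' each fold is fitted once and scored at every component count, and the
#' count minimizing RMSE of the held-out predictions is returned.
#'
#' @param X,y training data.
#' @param lv_max largest component count to consider (capped by the fold
#'   training size and band count).
#' @param folds `"loo"` (default) or an integer fold count; k-fold
#'   assignment is deterministic (round-robin over samples).
#' @return list with `n_lv` (the minimizing count), `rmse_cv` (vector over
#'   component counts) and `predictions` (held-out, at the chosen count).
#' @export
select_plsr_lv <- function(X, y, lv_max = 20, folds = "loo") {
  X <- as.matrix(X); y <- as.numeric(y)
  n <- nrow(X)
  fold_id <- if (identical(folds, "loo")) seq_len(n)
             else rep(seq_len(folds), length.out = n)
  n_folds <- max(fold_id)
  lv_max <- min(lv_max, ncol(X), n - max(table(fold_id)) - 1L)
  if (lv_max < 1) stop_invalid("not enough samples for cross-validation")
  preds <- matrix(NA_real_, n, lv_max)
  for (f in seq_len(n_folds)) {
    hold <- fold_id == f
    m <- fit_plsr(X[!hold, , drop = FALSE], y[!hold], n_lv = lv_max)
    for (k in seq_len(m$n_lv)) {
      preds[hold, k] <- predict(m, X[hold, , drop = FALSE], n_lv = k)
    }
  }
  ok <- colSums(is.na(preds)) == 0
  rmse_cv <- sqrt(colMeans((preds - y)^2))
  rmse_cv[!ok] <- Inf
  n_lv <- which.min(rmse_cv)
  list(n_lv = n_lv, rmse_cv = rmse_cv, predictions = preds[, n_lv])
}
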