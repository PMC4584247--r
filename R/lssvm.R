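# Least-squares support vector machine regression.
#
# Training solves the KKT linear system of the equality-constrained
# least-squares SVM:
#
#   [ 0   1'          ] [ b     ]   [ 0 ]
#   [ 1   K + I/gamma ] [ alpha ] = [ y ]
#
# with kernel matrix K_kl = K(x_k, x_l). Predictions are
# y(x) = sum_k alpha_k K(x, x_k) + b. The dual coefficients satisfy
# sum(alpha) = 0. RBF kernel convention: K(x, z) = exp(-||x - z||^2 /
# sigma2) (sigma2, "the bandwidth", in the denominator with no factor 2;
# exp(-d^2 / (2 sigma^2)) is a common alternative — mind the convention
# when importing tuned parameters).

kernel_matrix <- function(X1, X2, kernel, sigma2 = NULL) {
  X1 <- as.matrix(X1); X2 <- as.matrix(X2)
  if (kernel == "linear") {
    return(tcrossprod(X1, X2))
  }
  # squared Euclidean distances via the expansion trick
  d2 <- outer(rowSums(X1^2), rowSums(X2^2), "+") - 2 * tcrossprod(X1, X2)
  d2[d2 < 0] <- 0
  exp(-d2 / sigma2)
}

#' Fit an LS-SVM regression model
#'
#' @param X numeric samples x bands matrix.
#' @param y numeric response (degrees Brix).
#' @param kernel `"linear"` or `"rbf"`.
#' @param gamma regularization parameter (> 0); larger values weight the
#'   training-error term more heavily (less regularization).
#' @param sigma2 RBF bandwidth (> 0); ignored for the linear kernel.
#' @param wavelengths optional band-centre wavelengths (nm) carried on the
#'   model.
#' @return an object of class `lssvm_model`: dual coefficients `alpha`
#'   (summing to zero), bias `b`, the kernel specification and the
#'   training inputs.
#' @examples
#' X <- matrix(rnorm(30), 10, 3)
#' y <- sin(X[, 1]) + rnorm(10, sd = 0.05)
#' m <- fit_lssvm(X, y, kernel = "rbf", gamma = 100, sigma2 = 2)
#' sum(m$alpha)
#' @export
fit_lssvm <- function(X, y, kernel = c("linear", "rbf"), gamma = 1,
                      sigma2 = NULL, wavelengths = NULL) {
  kernel <- match.arg(kernel)
  X <- as.matrix(X); y <- as.numeric(y)
  n <- nrow(X)
  if (length(y) != n) stop_invalid("nrow(X) != length(y)")
  if (!(gamma > 0)) stop_invalid("`gamma` must be positive")
  if (kernel == "rbf" && (is.null(sigma2) || !(sigma2 > 0))) {
    stop_invalid("`sigma2` must be positive for the rbf kernel")
  }
  K <- kernel_matrix(X, X, kernel, sigma2)
  A <- rbind(c(0, rep(1, n)),
             cbind(1, K + diag(n) / gamma))
  rc <- rcond(A)
  if (!is.finite(rc) || rc < .Machine$double.eps) {
    stop(sprintf(
      "numerically singular LS-SVM system (reciprocal condition %.3e)", rc),
      call. = FALSE)
  }
  z <- solve(A, c(0, y))
  structure(list(
    alpha = z[-1], b = z[1],
    kernel = kernel, gamma = gamma,
    sigma2 = if (kernel == "rbf") sigma2 else NULL,
    X = X, y = y,
    wavelengths = wavelengths,
    system_rcond = rc
  ), class = "lssvm_model")
}

#' Predict from an LS-SVM model
#'
#' @param object a [fit_lssvm()] model.
#' @param newdata samples x bands matrix.
#' @param ... unused.
#' @return numeric vector of predictions (degrees Brix).
#' @export
predict.lssvm_model <- function(object, newdata, ...) {
  newdata <- if (is.null(dim(newdata))) matrix(newdata, nrow = 1) else as.matrix(newdata)
  if (ncol(newdata) != ncol(object$X)) {
    stop_invalid("newdata has %d bands, model expects %d",
                 ncol(newdata), ncol(object$X))
  }
  Kn <- kernel_matrix(newdata, object$X, object$kernel, object$sigma2)
  as.numeric(Kn %*% object$alpha + object$b)
}

#' @export
coef.lssvm_model <- function(object, ...) {
  c(b = object$b, alpha = object$alpha)
}

#' @export
fitted.lssvm_model <- function(object, ...) predict(object, object$X)

#' @export
residuals.lssvm_model <- function(object, ...) {
  # from the stationarity condition alpha_k = gamma * e_k
  object$alpha / object$gamma
}

#' @export
print.lssvm_model <- function(x, ...) {
  cat(sprintf("<lssvm_model> %s kernel, gamma = %.4g%s, %d support samples\n",
              x$kernel, x$gamma,
              if (!is.null(x$sigma2)) sprintf(", sigma2 = %.4g", x$sigma2) else "",
              nrow(x$X)))
  invisible(x)
}

# Closed-form leave-one-out residuals of an LS-SVM fit: with A the full
# (n+1) KKT matrix, the held-out residual of sample i is
#   y_i - yhat_i^(-i) = alpha_i / (A^{-1})_{i+1, i+1}.
# One factorization scores the whole LOO loop; verified against the
# literal n-refit loo_cv in the test suite.
lssvm_loo_residuals <- function(X, y, kernel, gamma, sigma2 = NULL) {
  n <- nrow(X)
  K <- kernel_matrix(X, X, kernel, sigma2)
  A <- rbind(c(0, rep(1, n)),
             cbind(1, K + diag(n) / gamma))
  Ainv <- tryCatch(solve(A), error = function(e) NULL)
  if (is.null(Ainv)) return(rep(NA_real_, n))
  z <- Ainv %*% c(0, y)
  alpha <- z[-1]
  alpha / diag(Ainv)[-1]
}

#' Grid search for LS-SVM hyperparameters
#'
#' Exhaustively evaluates every (gamma, sigma2) grid point by
#' leave-one-out cross-validation RMSE and returns the minimizer; ties
#' break to the smallest gamma, then the smallest sigma2. For the linear
#' kernel the sigma2 grid is ignored (the kernel has no bandwidth). The
#' LOO residuals use the closed-form identity of the LS-SVM system (one
#' factorization per grid point, no refitting).
#'
#' @param X,y training data.
#' @param kernel `"linear"` or `"rbf"`.
#' @param gamma_grid candidate regularization values; default 13
#'   log-spaced points over 1e0..1e9.
#' @param sigma2_grid candidate RBF bandwidths; default 17 log-spaced
#'   points over 1e-2..1e6.
#' @return list with `gamma`, `sigma2` (NULL for linear), `rmse_cv`, and
#'   `evaluations` (a data.frame of every grid point and its score).
#' @export
grid_search_lssvm <- function(X, y, kernel = c("linear", "rbf"),
                              gamma_grid = 10^seq(0, 9, length.out = 13),
                              sigma2_grid = 10^seq(-2, 6, length.out = 17)) {
  kernel <- match.arg(kernel)
  X <- as.matrix(X); y <- as.numeric(y)
  if (length(gamma_grid) == 0) stop_invalid("empty gamma grid")
  if (kernel == "rbf" && length(sigma2_grid) == 0) {
    stop_invalid("empty sigma2 grid")
  }
  gamma_grid <- sort(gamma_grid)
  if (kernel == "linear") {
    grid <- data.frame(gamma = gamma_grid, sigma2 = NA_real_)
  } else {
    sigma2_grid <- sort(sigma2_grid)
    grid <- expand.grid(sigma2 = sigma2_grid, gamma = gamma_grid)[, c("gamma", "sigma2")]
    grid <- grid[order(grid$gamma, grid$sigma2), ]
  }
  grid$rmse_cv <- vapply(seq_len(nrow(grid)), function(i) {
    res <- lssvm_loo_residuals(X, y, kernel, grid$gamma[i],
                               if (kernel == "rbf") grid$sigma2[i] else NULL)
    sqrt(mean(res^2))
  }, numeric(1))
  finite <- is.finite(grid$rmse_cv)
  if (!any(finite)) stop("all grid points numerically singular", call. = FALSE)
  best <- which(finite)[which.min(grid$rmse_cv[finite])] # order = ties rule
  list(gamma = grid$gamma[best],
       sigma2 = if (kernel == "rbf") grid$sigma2[best] else NULL,
       rmse_cv = grid$rmse_cv[best],
       evaluations = grid)
}
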