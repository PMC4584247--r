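test_that("PLS1 captures a rank-one linear relation with one component", {
  set.seed(1)
  direction <- rnorm(6)
  scores <- rnorm(20)
  X <- outer(scores, direction)
  y <- 2 * scores + 5
  m <- fit_plsr(X, y, n_lv = 1)
  expect_lt(max(abs(m$residuals)), 1e-10)
})

test_that("PLS1 at full rank equals the least-squares oracle", {
  set.seed(2)
  X <- matrix(rnorm(80), 10, 8)
  y <- as.numeric(X %*% rnorm(8) + rnorm(10))
  m <- fit_plsr(X, y, n_lv = 8)
  # normal-equations oracle
  Z <- cbind(1, X)
  beta <- solve(crossprod(Z), crossprod(Z, y))
  expect_equal(unname(coef(m)), as.numeric(beta), tolerance = 1e-8)
  expect_equal(predict(m, X), as.numeric(Z %*% beta), tolerance = 1e-8)
})

test_that("PLS1 regression vector under orthonormal X is X'y", {
  # orthonormal columns, centred so centring is a no-op
  set.seed(10)
  Q <- qr.Q(qr(matrix(rnorm(24), 6, 4)))
  Q <- sweep(Q, 2, colMeans(Q)) # centre
  # re-orthonormalize the centred columns
  Q <- qr.Q(qr(Q))[, 1:3]
  stopifnot(max(abs(colMeans(Q))) < 1e-10)
  y <- as.numeric(Q %*% c(1, -2, 3))
  m <- fit_plsr(Q, y, n_lv = 3)
  expect_equal(m$coefficients, as.numeric(crossprod(Q, y - mean(y))),
               tolerance = 1e-8)
})

test_that("adding latent variables never worsens the training fit", {
  set.seed(3)
  X <- matrix(rnorm(40 * 12), 40, 12)
  y <- rowSums(X[, 1:4]) + rnorm(40, sd = 0.5)
  m <- fit_plsr(X, y, n_lv = 10)
  rmse <- vapply(seq_len(m$n_lv), function(k) {
    sqrt(mean((predict(m, X, n_lv = k) - y)^2))
  }, numeric(1))
  expect_true(all(diff(rmse) <= 1e-10))
})

test_that("PLS1 rejects invalid inputs", {
  X <- matrix(rnorm(20), 5, 4)
  expect_error(fit_plsr(X, rep(1, 5), n_lv = 2), "zero variance")
  expect_error(fit_plsr(X, rnorm(5), n_lv = 5), "n_lv")
  expect_error(fit_plsr(X, rnorm(5), n_lv = 0), "n_lv")
})

test_that("LS-SVM matches the literal KKT-system oracle", {
  set.seed(4)
  for (kernel in c("linear", "rbf")) {
    X <- matrix(rnorm(18 * 3), 18, 3)
    y <- sin(X[, 1]) + 0.5 * X[, 2] + rnorm(18, sd = 0.1)
    m <- fit_lssvm(X, y, kernel, gamma = 50,
                   sigma2 = if (kernel == "rbf") 2 else NULL)
    o <- lssvm_dense_oracle(X, y, kernel, gamma = 50,
                            sigma2 = if (kernel == "rbf") 2 else NULL)
    expect_equal(m$alpha, o$alpha, tolerance = 1e-8)
    expect_equal(m$b, o$b, tolerance = 1e-8)
    # dual constraint
    expect_lt(abs(sum(m$alpha)), 1e-8 * sqrt(sum(m$alpha^2)))
  }
})

test_that("the hand-solved 3x3 LS-SVM system is reproduced", {
  # x = {-1, +1}, y = {-1, +1}, linear kernel, gamma = 1:
  # K = [[1,-1],[-1,1]], A = [[0,1,1],[1,2,-1],[1,-1,2]], rhs (0,-1,1)
  # alpha1 + alpha2 = 0; b + 3 alpha1 = -1; b - 3 alpha1 = 1
  # => b = 0, alpha = (-1/3, 1/3)
  m <- fit_lssvm(matrix(c(-1, 1), 2, 1), c(-1, 1), "linear", gamma = 1)
  expect_equal(m$b, 0, tolerance = 1e-12)
  expect_equal(m$alpha, c(-1 / 3, 1 / 3), tolerance = 1e-12)
})

test_that("RBF kernel is 1 at zero distance and the ridge limit interpolates", {
  x <- matrix(rnorm(5), 1, 5)
  expect_equal(as.numeric(kernel_matrix(x, x, "rbf", sigma2 = 3)), 1)

  set.seed(5)
  X <- matrix(rnorm(30), 10, 3)
  y <- as.numeric(X %*% c(1, -2, 0.5) + 3)
  m <- fit_lssvm(X, y, "linear", gamma = 1e8)
  expect_lt(max(abs(predict(m, X) - y)), 1e-3 * diff(range(y)))
})

test_that("leave-one-out CV performs n held-out fits", {
  set.seed(6)
  X <- matrix(rnorm(24), 8, 3)
  y <- rnorm(8, mean = 5)

  # constant recipe
  cv_const <- loo_cv(X, y, function(X, y) function(newdata) 4)
  expect_equal(cv_const$rmse_cv, sqrt(mean((y - 4)^2)))

  # mean-predictor recipe at n = 3: held-out i predicted by the other two
  y3 <- c(1, 2, 6)
  cv_mean <- loo_cv(X[1:3, ], y3, function(X, y) function(newdata) mean(y))
  expect_equal(cv_mean$predictions,
               c(mean(y3[-1]), mean(y3[-2]), mean(y3[-3])))

  # PLSR recipe beats the mean predictor on noise-free linear data
  tb <- linear_table(n = 20, p = 5, planted = 2, noise_sd = 0)
  cv_pls <- loo_cv(tb$X, tb$y, function(X, y) fit_plsr(X, y, n_lv = 1))
  expect_lt(cv_pls$rmse_cv,
            loo_cv(tb$X, tb$y, function(X, y) function(nd) mean(y))$rmse_cv)

  expect_error(loo_cv(X[1:2, ], y[1:2], function(X, y) function(nd) 1),
               "n >= 3")
})

test_that("the closed-form LS-SVM LOO equals the brute-force refits", {
  set.seed(7)
  X <- matrix(rnorm(36), 12, 3)
  y <- X[, 1]^2 + rnorm(12, sd = 0.1)
  for (kernel in c("linear", "rbf")) {
    s2 <- if (kernel == "rbf") 4 else NULL
    fast <- hsitss:::lssvm_loo_residuals(X, y, kernel, gamma = 20, sigma2 = s2)
    brute <- loo_cv(X, y, function(X, y) {
      fit_lssvm(X, y, kernel, gamma = 20, sigma2 = s2)
    })
    expect_equal(y - brute$predictions, fast, tolerance = 1e-9)
  }
})

test_that("grid search enumerates exhaustively and breaks ties low", {
  set.seed(8)
  X <- matrix(rnorm(30), 10, 3)
  y <- rnorm(10, 5)

  single <- grid_search_lssvm(X, y, "rbf", gamma_grid = 7, sigma2_grid = 2)
  expect_equal(single$gamma, 7)
  expect_equal(single$sigma2, 2)

  two <- grid_search_lssvm(X, y, "rbf", gamma_grid = 5, sigma2_grid = c(1, 10))
  expect_equal(nrow(two$evaluations), 2)

  lin <- grid_search_lssvm(X, y, "linear", gamma_grid = c(1, 10),
                           sigma2_grid = c(1, 2, 3))
  expect_equal(nrow(lin$evaluations), 2) # sigma2 grid ignored
  expect_null(lin$sigma2)
})

test_that("grid search recovers a planted RBF bandwidth within one step", {
  set.seed(9)
  n <- 40
  X <- matrix(rnorm(n * 2), n, 2)
  centres <- X[1:5, ]
  true_s2 <- 1
  K <- hsitss:::kernel_matrix(X, centres, "rbf", sigma2 = true_s2)
  y <- as.numeric(K %*% c(2, -1, 1.5, -2, 1)) + rnorm(n, sd = 0.02)
  grid_s2 <- 10^seq(-2, 2, by = 0.5)
  gs <- grid_search_lssvm(X, y, "rbf", gamma_grid = 10^(1:4),
                          sigma2_grid = grid_s2)
  expect_lte(abs(log10(gs$sigma2) - log10(true_s2)), 0.5 + 1e-9)
})

test_that("metrics follow the R/RMSE definitions", {
  y <- c(2, 4, 6, 9)
  expect_equal(compute_metrics(y, y), c(R = 1, RMSE = 0))
  expect_equal(compute_metrics(y, y + 1), c(R = 1, RMSE = 1))
  expect_equal(compute_metrics(c(1, 2, 3), c(2, 2, 2))[["RMSE"]],
               sqrt(2 / 3))
  expect_error(compute_metrics(rep(1, 3), c(1, 2, 3)), "constant")
  expect_error(compute_metrics(1:3, 1:4), "length")
})

test_that("relative changes reproduce the model-comparison arithmetic", {
  expect_equal(relative_change(0.956, 0.925), -3.24)
  expect_equal(relative_change(0.430, 0.557), 29.5)
  expect_equal(relative_change(460, 23), -95.0)
  expect_error(relative_change(0, 1), "nonzero")
})

test_that("model serialization round trips predictions", {
  tb <- linear_table(n = 20, p = 6, noise_sd = 0.05)
  newX <- tb$X[1:4, ]

  pm <- fit_plsr(tb$X, tb$y, n_lv = 3, wavelengths = tb$grid)
  f <- tempfile(fileext = ".json")
  serialize_model(pm, f)
  back <- deserialize_model(f)
  expect_equal(predict(back, newX), predict(pm, newX), tolerance = 1e-10)

  lm_ <- fit_lssvm(tb$X, tb$y, "rbf", gamma = 10, sigma2 = 5,
                   wavelengths = tb$grid)
  serialize_model(lm_, f)
  back2 <- deserialize_model(f)
  expect_equal(predict(back2, newX), predict(lm_, newX), tolerance = 1e-10)
  unlink(f)
})
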