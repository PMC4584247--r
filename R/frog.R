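# Random Frog wavelength selection.
#
# A pseudo-MCMC search over variable subsets in the spirit of reversible
# jump MCMC: from the current subset V0 (size Q0) a candidate V* of size
# Q* ~ round(Normal(Q0, theta * Q0)) is proposed by adding randomly drawn
# bands (an omega-times oversized pool, then keeping the bands with the
# largest absolute PLS coefficients) or by shrinking V0 the same way.
# Candidates with better cross-validated sub-model error are always
# accepted; worse ones with probability min(eta, eta * f(V0) / f(V*)).
# Each band's selection probability (SP) is the fraction of iterations
# whose retained subset contains it.

#' Random Frog parameters
#'
#' @param T iterations; 10,000 is the usual production scale, a few
#'   hundred suffice for smoke checks.
#' @param Q initial subset size (`1 <= Q <= n_bands`).
#' @param theta variance factor of the candidate-size normal distribution
#'   (> 0): the candidate size is drawn from Normal(Q0, theta * Q0).
#' @param omega candidate-pool multiplier (>= 1): when growing by k bands,
#'   omega * k random bands compete for the k slots.
#' @param eta upper bound of the acceptance probability for worse
#'   candidates (0 < eta <= 1).
#' @param n_lv_max maximum latent variables in PLS sub-models.
#' @param cv_folds folds of the sub-model fitness cross-validation.
#' @param seed integer seed; all randomness flows from one generator.
#' @return an object of class `frog_params`.
#' @export
frog_params <- function(T = 10000L, Q = 50L, theta = 0.3, omega = 3,
                        eta = 0.1, n_lv_max = 10L, cv_folds = 5L,
                        seed = 1L) {
  if (T < 1) stop_invalid("`T` must be >= 1")
  if (Q < 1) stop_invalid("`Q` must be >= 1")
  if (!(theta > 0)) stop_invalid("`theta` must be positive")
  if (omega < 1) stop_invalid("`omega` must be >= 1")
  if (!(eta > 0 && eta <= 1)) stop_invalid("`eta` must be in (0, 1]")
  structure(list(T = as.integer(T), Q = as.integer(Q), theta = theta,
                 omega = omega, eta = eta, n_lv_max = as.integer(n_lv_max),
                 cv_folds = as.integer(cv_folds), seed = as.integer(seed)),
            class = "frog_params")
}

# k-fold CV RMSE of a PLS1 sub-model on the band subset `bands`.
frog_fitness <- function(X, y, bands, fold_id, n_lv_max) {
  n <- nrow(X)
  preds <- rep(NA_real_, n)
  for (f in seq_len(max(fold_id))) {
    hold <- fold_id == f
    n_tr <- sum(!hold)
    n_lv <- min(n_lv_max, length(bands), n_tr - 1L)
    m <- tryCatch(
      fit_plsr(X[!hold, bands, drop = FALSE], y[!hold], n_lv = n_lv),
      error = function(e) NULL)
    if (is.null(m)) return(Inf)
    preds[hold] <- predict(m, X[hold, bands, drop = FALSE])
  }
  sqrt(mean((preds - y)^2))
}

# rank bands of `pool` by |PLS coefficient| on X[, pool], keep the top k
frog_top_bands <- function(X, y, pool, k, n_lv_max) {
  n_lv <- min(n_lv_max, length(pool), nrow(X) - 1L)
  m <- tryCatch(fit_plsr(X[, pool, drop = FALSE], y, n_lv = n_lv),
                error = function(e) NULL)
  if (is.null(m)) {
    return(pool[seq_len(k)]) # degenerate sub-model: keep the first k
  }
  pool[order(abs(m$coefficients), decreasing = TRUE)[seq_len(k)]]
}

#' Run the Random Frog wavelength search
#'
#' @param table a [spectra_table()] with at least `cv_folds` samples.
#' @param params a [frog_params()].
#' @return an object of class `frog_result`: `sp` (selection probability
#'   per band, `inclusion_counts / T`), `inclusion_counts`, `trace` (the
#'   retained subset size at each iteration), `wavelength`, `T` and
#'   `params`.
#' @export
run_random_frog <- function(table, params = frog_params()) {
  stopifnot(inherits(table, "spectra_table"), inherits(params, "frog_params"))
  X <- table$X; y <- table$y
  n <- nrow(X); p <- ncol(X)
  if (n < params$cv_folds) {
    stop_invalid("table has %d samples, fewer than cv_folds = %d",
                 n, params$cv_folds)
  }
  if (params$Q > p) stop_invalid("`Q` exceeds the band count %d", p)

  with_seed(params$seed, {
    fold_id <- sample(rep(seq_len(params$cv_folds), length.out = n))
    V0 <- sort(sample.int(p, params$Q))
    f0 <- frog_fitness(X, y, V0, fold_id, params$n_lv_max)
    counts <- integer(p)
    trace <- integer(params$T)
    for (it in seq_len(params$T)) {
      Q0 <- length(V0)
      Q_star <- round(stats::rnorm(1, Q0, params$theta * Q0))
      Q_star <- max(1L, min(p, as.integer(Q_star)))
      if (Q_star == Q0) {
        V_star <- V0
        f_star <- f0
      } else {
        if (Q_star > Q0) {
          complement <- setdiff(seq_len(p), V0)
          n_draw <- min(length(complement),
                        ceiling(params$omega * (Q_star - Q0)))
          pool <- c(V0, sample(complement, n_draw))
          Q_star <- min(Q_star, length(pool))
        } else {
          pool <- V0
        }
        V_star <- sort(frog_top_bands(X, y, pool, Q_star, params$n_lv_max))
        f_star <- frog_fitness(X, y, V_star, fold_id, params$n_lv_max)
        accept <- if (f_star <= f0) TRUE
                  else stats::runif(1) < min(params$eta, params$eta * f0 / f_star)
        if (accept) {
          V0 <- V_star
          f0 <- f_star
        }
      }
      counts[V0] <- counts[V0] + 1L
      trace[it] <- length(V0)
    }
    structure(list(sp = counts / params$T,
                   inclusion_counts = counts,
                   trace = trace,
                   wavelength = table$grid,
                   T = params$T,
                   params = params),
              class = "frog_result")
  })
}

#' @export
print.frog_result <- function(x, ...) {
  cat(sprintf("<frog_result> %d bands, T = %d; SP range [%.3f, %.3f]\n",
              length(x$sp), x$T, min(x$sp), max(x$sp)))
  invisible(x)
}

#' Select important wavelengths by SP cut-off
#'
#' @param result a [run_random_frog()] result (or a numeric SP vector).
#' @param grid wavelengths in nm (taken from `result` if absent).
#' @param cutoff selection-probability cut-off in `[0, 1]`; usual working
#'   values are 0.7 (larger set) and 0.85 (smaller set).
#' @return data.frame with columns `band` (index), `wavelength` (nm) and
#'   `sp`, containing all bands with `sp >= cutoff`, ordered by descending
#'   SP with ties broken by ascending wavelength. May be empty.
#' @export
select_by_cutoff <- function(result, grid = NULL, cutoff = 0.7) {
  sp <- if (inherits(result, "frog_result")) result$sp else as.numeric(result)
  if (is.null(grid)) {
    if (!inherits(result, "frog_result")) {
      stop_invalid("`grid` required when `result` is a bare SP vector")
    }
    grid <- result$wavelength
  }
  if (length(grid) != length(sp)) stop_invalid("grid/sp length mismatch")
  if (cutoff < 0 || cutoff > 1) stop_invalid("`cutoff` must be in [0, 1]")
  keep <- which(sp >= cutoff)
  keep <- keep[order(-sp[keep], grid[keep])]
  data.frame(band = keep, wavelength = grid[keep], sp = sp[keep])
}
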