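# Fixture builders shared across test files. Everything is generated in
# code under fixed seeds; no data files.

# small capture with known ground truth
tiny_capture <- function(n_blobs = 3, n_bands = 64, seed = 11,
                         params = spectral_model_params()) {
  grid <- make_wavelength_grid(n_bands, 380, 1030)
  render_capture(draw_tss_values(n_blobs, seed + 1), grid,
                 capture_geometry(rows = 64, cols = 64, blob_radius = 6,
                                  n_blobs = n_blobs),
                 params, seed = seed)
}

noise_free_params <- function() {
  spectral_model_params(noise_sd = 0, scatter_sd = 0, saturation_rate = 0)
}

# spectra table with an exactly linear response in a known band set
linear_table <- function(n = 40, p = 12, planted = c(2, min(4, p)),
                         noise_sd = 0, seed = 5) {
  set.seed(seed)
  X <- matrix(rnorm(n * p), n, p)
  y <- rowSums(X[, planted, drop = FALSE]) + 6 + rnorm(n, sd = noise_sd)
  spectra_table(X, y, 400 + seq_len(p))
}

# literal assembly + qr.solve of the LS-SVM KKT system: the independent
# oracle for fit_lssvm (loops, no shared code path)
lssvm_dense_oracle <- function(X, y, kernel, gamma, sigma2 = NULL) {
  n <- nrow(X)
  K <- matrix(0, n, n)
  for (k in seq_len(n)) {
    for (l in seq_len(n)) {
      K[k, l] <- if (kernel == "linear") sum(X[k, ] * X[l, ])
                 else exp(-sum((X[k, ] - X[l, ])^2) / sigma2)
    }
  }
  A <- matrix(0, n + 1, n + 1)
  A[1, 2:(n + 1)] <- 1
  A[2:(n + 1), 1] <- 1
  A[2:(n + 1), 2:(n + 1)] <- K + diag(n) / gamma
  z <- qr.solve(A, c(0, y))
  list(b = z[1], alpha = z[-1])
}
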