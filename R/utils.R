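# Internal helpers shared across modules.

#' Run code with a temporary RNG state
#'
#' Evaluates `expr` under `set.seed(seed)` and restores the caller's RNG
#' state afterwards, so seeded generators do not perturb user code.
#'
#' @param seed single integer seed.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
#' @noRd
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("`seed` must be a single integer", call. = FALSE)
  }
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

# Derive k child seeds from a master seed, each < 2^31, deterministically.
derive_seeds <- function(master, k) {
  with_seed(master, sample.int(.Machine$integer.max - 1L, k))
}

# Index of the grid band nearest to each requested wavelength (nm).
nearest_band <- function(grid, wavelengths) {
  vapply(wavelengths, function(w) which.min(abs(grid - w)), integer(1))
}

stop_invalid <- function(...) stop(sprintf(...), call. = FALSE)
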