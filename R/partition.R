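# SpectraTable container and SPXY calibration/prediction partitioning.

#' Spectra table
#'
#' Samples x bands matrix of mean ROI reflectance spectra together with the
#' per-sample reference response (TSS, degrees Brix).
#'
#' @param X numeric samples x bands matrix, no missing values.
#' @param y numeric response vector, one value per row of `X`.
#' @param grid wavelength grid in nm, one value per column of `X`.
#' @param sample_ids optional character ids, one per sample.
#' @return an object of class `spectra_table`.
#' @export
spectra_table <- function(X, y, grid, sample_ids = NULL) {
  X <- as.matrix(X)
  if (nrow(X) != length(y)) stop_invalid("nrow(X) != length(y)")
  if (ncol(X) != length(grid)) stop_invalid("ncol(X) != length(grid)")
  if (anyNA(X) || anyNA(y)) stop_invalid("spectra table may not contain NA")
  if (is.null(sample_ids)) sample_ids <- sprintf("S%03d", seq_len(nrow(X)))
  if (length(sample_ids) != nrow(X)) stop_invalid("one id per sample required")
  structure(list(X = unname(X), y = as.numeric(y),
                 grid = as.numeric(grid),
                 sample_ids = as.character(sample_ids)),
            class = "spectra_table")
}

#' @export
print.spectra_table <- function(x, ...) {
  cat(sprintf("<spectra_table> %d samples x %d bands (%.1f-%.1f nm), y in [%.2f, %.2f]\n",
              nrow(x$X), ncol(x$X), min(x$grid), max(x$grid),
              min(x$y), max(x$y)))
  invisible(x)
}

#' SPXY calibration/prediction split
#'
#' Sample-set partitioning based on joint x-y distances: Kennard-Stone
#' selection on the summed normalized distance
#' `d(i,j) = d_x(i,j)/max(d_x) + d_y(i,j)/max(d_y)`, with Euclidean `d_x`
#' on the spectra and `|y_i - y_j|` on the response. Selection seeds with
#' the pair at maximal joint distance, then repeatedly adds the sample
#' whose minimum distance to the already-selected set is largest
#' (maximin), until `n_calibration` samples are selected; the remainder
#' forms the prediction set. Deterministic; ties break to the smallest
#' original sample index. If all spectra (or all responses) are identical
#' the non-degenerate distance alone is used.
#'
#' @param table a [spectra_table()].
#' @param n_calibration calibration-set size, `2 <= n_calibration < n`.
#' @return an object of class `split_assignment`: list with sorted integer
#'   vectors `calibration` and `prediction` (disjoint, covering all
#'   samples).
#' @export
spxy_split <- function(table, n_calibration) {
  stopifnot(inherits(table, "spectra_table"))
  n <- nrow(table$X)
  if (n_calibration < 2 || n_calibration >= n) {
    stop_invalid("`n_calibration` must satisfy 2 <= n_calibration < %d", n)
  }
  dx <- as.matrix(stats::dist(table$X))
  dy <- abs(outer(table$y, table$y, "-"))
  mx <- max(dx); my <- max(dy)
  d <- if (mx == 0 && my == 0) {
    stop_invalid("all samples identical in both x and y")
  } else if (mx == 0) {
    dy / my
  } else if (my == 0) {
    dx / mx
  } else {
    dx / mx + dy / my
  }

  # seed: pair of maximal joint distance, ties to smallest indices
  # (column-major which.max scans j-major over [i + (j-1)n]; take the
  # lexicographically smallest maximal pair explicitly)
  best <- which(d == max(d), arr.ind = TRUE)
  best <- best[order(pmin(best[, 1], best[, 2]),
                     pmax(best[, 1], best[, 2])), , drop = FALSE]
  selected <- sort(unique(as.integer(best[1, ])))
  min_d <- pmin(d[, selected[1]], d[, selected[2]])
  min_d[selected] <- -Inf
  while (length(selected) < n_calibration) {
    nxt <- which.max(min_d) # ties -> smallest index
    selected <- c(selected, nxt)
    min_d <- pmin(min_d, d[, nxt])
    min_d[nxt] <- -Inf
  }
  calibration <- sort(as.integer(selected))
  structure(list(calibration = calibration,
                 prediction = setdiff(seq_len(n), calibration)),
            class = "split_assignment")
}

#' @export
print.split_assignment <- function(x, ...) {
  cat(sprintf("<split_assignment> %d calibration / %d prediction samples\n",
              length(x$calibration), length(x$prediction)))
  invisible(x)
}

#' Subset a spectra table
#'
#' @param table a [spectra_table()].
#' @param idx integer sample indices.
#' @return the subsetted [spectra_table()].
#' @export
subset_table <- function(table, idx) {
  stopifnot(inherits(table, "spectra_table"))
  spectra_table(table$X[idx, , drop = FALSE], table$y[idx], table$grid,
                table$sample_ids[idx])
}
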