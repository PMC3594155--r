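#' Remove low-coverage bins before normalization
#'
#' SCN balancing gives every region equal weight, so bins with very few
#' reads must be removed first or their noise is amplified. A bin is
#' removed when the Euclidean norm of its row (intra: row = column) is
#' strictly below `threshold`; its row and, for intra matrices, matching
#' column are zeroed and recorded in the removed-bin mask. Typical
#' thresholds: 10 for inter-chromosomal maps at 1 Mb and intra maps at
#' 10 Mb, 100 for intra maps at 1 Mb.
#'
#' @param m A raw-count `contact_matrix`.
#' @param threshold Euclidean-norm cutoff (default 10).
#' @return The matrix with low-coverage bins zeroed and `removed_rows` /
#'   `removed_cols` updated.
#' @export
filter_low_coverage_bins <- function(m, threshold = 10) {
  stopifnot(inherits(m, "contact_matrix"), threshold >= 0)
  v <- m$values
  rn <- sqrt(rowSums(v^2))
  cn <- sqrt(colSums(v^2))
  rr <- which(rn < threshold)
  rc <- if (is_intra(m)) rr else which(cn < threshold)
  if (length(rr) == nrow(v) || length(rc) == ncol(v)) {
    abort("all bins fall below the coverage threshold; nothing to normalize.")
  }
  v[rr, ] <- 0
  v[, rc] <- 0
  m$values <- v
  m$removed_rows <- sort(unique(c(m$removed_rows, rr - 1L)))
  m$removed_cols <- sort(unique(c(m$removed_cols, rc - 1L)))
  m
}

#' Sequential component normalization (SCN)
#'
#' Iteratively divides each column by its Euclidean norm, then each row by
#' its Euclidean norm, until the matrix is symmetric (square matrices;
#' maximum absolute asymmetry below `tolerance`) or, for rectangular
#' inter-chromosomal matrices, until the iterate stops changing. At
#' convergence every surviving row has unit Euclidean norm. Zero rows or
#' columns are left untouched and recorded as removed bins.
#'
#' @param m A `contact_matrix` with low-coverage bins already removed (see
#'   [filter_low_coverage_bins()]).
#' @param tolerance Convergence tolerance on `max|M - t(M)|` (default 1e-6).
#' @param max_iter Maximum number of column+row passes (default 1000). If
#'   reached without convergence a warning is issued and the last iterate is
#'   returned with attribute `converged = FALSE`.
#' @return A `contact_matrix` of kind `"scn"` (or `"<kind>_scn"`), with
#'   fields `converged` and `iterations`.
#' @export
scn_normalize <- function(m, tolerance = 1e-6, max_iter = 1000) {
  stopifnot(inherits(m, "contact_matrix"), tolerance > 0, max_iter >= 1)
  v <- m$values
  if (all(v == 0)) abort("matrix is all zero; cannot normalize.")
  square <- nrow(v) == ncol(v)
  norm_div <- function(x, norms) {
    norms[norms == 0] <- 1  # zero vectors left as zero
    x / norms
  }
  converged <- FALSE
  it <- 0L
  repeat {
    it <- it + 1L
    prev <- v
    v <- t(norm_div(t(v), sqrt(colSums(v^2))))  # columns
    v <- norm_div(v, sqrt(rowSums(v^2)))        # rows
    delta <- if (square) max(abs(v - t(v))) else max(abs(v - prev))
    if (delta < tolerance) {
      converged <- TRUE
      break
    }
    if (it >= max_iter) break
  }
  if (!converged) {
    warn(sprintf("SCN did not converge in %d iterations (last delta > %g).",
                 max_iter, tolerance))
  }
  # zero rows/cols that survived the coverage filter count as removed
  zr <- which(rowSums(abs(v)) == 0) - 1L
  zc <- which(colSums(abs(v)) == 0) - 1L
  m$values <- v
  m$removed_rows <- sort(unique(c(m$removed_rows, zr)))
  m$removed_cols <- sort(unique(c(m$removed_cols, if (is_intra(m)) zr else zc)))
  m$kind <- if (m$kind == "raw_counts") "scn" else paste0(m$kind, "_scn")
  m$converged <- converged
  m$iterations <- it
  m
}

#' Genomic-distance normalization of an intra-chromosomal matrix
#'
#' Divides each cell by the mean value of all non-removed cells at the same
#' genomic distance (diagonal offset), so that short-range abundance no
#' longer drowns long-range structure: after normalization the mean of
#' every populated offset is 1. Offsets whose mean is zero are left at
#' zero. Combine with SCN (`distance_normalize()` then [scn_normalize()])
#' for the distance-corrected balanced map.
#'
#' @param m An intra-chromosomal `contact_matrix` (raw or SCN-normalized).
#' @return A `contact_matrix` of kind suffixed `"_dist"`.
#' @export
distance_normalize <- function(m) {
  stopifnot(inherits(m, "contact_matrix"))
  if (!is_intra(m) || nrow(m$values) != ncol(m$values)) {
    abort("distance normalization applies to intra-chromosomal matrices.")
  }
  v <- m$values
  n <- nrow(v)
  keep <- setdiff(seq_len(n), m$removed_rows + 1L)
  row_i <- row(v); col_i <- col(v)
  off <- col_i - row_i
  usable <- row_i %in% keep & col_i %in% keep
  means <- vapply(0:(n - 1L), function(d) {
    cells <- v[off == d & usable]
    if (length(cells) == 0) 0 else mean(cells)
  }, 0)
  scale <- means[abs(off) + 1L]
  out <- ifelse(scale > 0, v / scale, 0)
  out <- matrix(out, n, n)
  out[!usable] <- 0
  m$values <- out
  m$kind <- paste0(m$kind, "_dist")
  m
}

#' Simple whole-matrix scalings
#'
#' Elementwise rescaling by whole-matrix statistics, used for side-by-side
#' comparison of contact maps: `x_over_avg` (`x/mean`), `minmax`
#' (`(x - min)/max`), or `zscore` (`(x - mean)/sd`).
#'
#' @param m A `contact_matrix`.
#' @param method One of `"x_over_avg"`, `"minmax"`, `"zscore"`.
#' @return A `contact_matrix` of kind `"simple_<method>"`.
#' @export
simple_normalize <- function(m, method = c("x_over_avg", "minmax", "zscore")) {
  method <- match.arg(method)
  stopifnot(inherits(m, "contact_matrix"))
  v <- m$values
  out <- switch(method,
    x_over_avg = {
      mu <- mean(v)
      if (mu == 0) abort("x_over_avg: matrix mean is zero.")
      v / mu
    },
    minmax = {
      mx <- max(v)
      if (mx == 0) abort("minmax: matrix maximum is zero.")
      (v - min(v)) / mx
    },
    zscore = {
      s <- sd(as.vector(v))
      if (s == 0) abort("zscore: matrix standard deviation is zero.")
      (v - mean(v)) / s
    }
  )
  m$values <- out
  m$kind <- paste0("simple_", method)
  m
}
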