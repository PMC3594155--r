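#' Pearson correlation matrix of a contact matrix
#'
#' Cell `(i, j)` is the Pearson correlation between rows `i` and `j` of the
#' contact matrix: regions in contact tend to share contact partners and so
#' correlate strongly, which amplifies the plaid (checkerboard) pattern of
#' open/closed chromatin compartments. Columns of removed bins are excluded
#' from every correlation; rows of removed bins, and constant rows whose
#' correlation is undefined, are set to 0 and flagged.
#'
#' @param m A square `contact_matrix` (intra, or normalized).
#' @return A `contact_matrix` of kind `"correlation"` with values in
#'   `[-1, 1]` and a field `undefined_bins` (0-based indices of rows with
#'   zero variance, removed bins included).
#' @export
correlation_matrix <- function(m) {
  stopifnot(inherits(m, "contact_matrix"))
  v <- m$values
  if (ncol(v) < 2) abort("need at least 2 columns to correlate rows.")
  if (nrow(v) != ncol(v)) abort("correlation matrix requires a square input.")
  keep_cols <- setdiff(seq_len(ncol(v)), m$removed_cols + 1L)
  x <- t(v[, keep_cols, drop = FALSE])  # columns = regions (rows of m)
  sds <- apply(x, 2, sd)
  undef <- which(sds == 0)
  cm <- suppressWarnings(cor(x))
  cm[undef, ] <- 0
  cm[, undef] <- 0
  diag(cm)[setdiff(seq_len(nrow(v)), undef)] <- 1
  m$values <- cm
  m$kind <- "correlation"
  m$undefined_bins <- sort(unique(c(undef - 1L, m$removed_rows)))
  m
}

#' Absolute difference between two correlation matrices
#'
#' `|C1 - C2|`, visualized as a heat map to localize conformational
#' differences between two samples.
#'
#' @param c1,c2 Correlation matrices on the same bin grid and removed-bin
#'   mask.
#' @return A `contact_matrix` of kind `"difference"`.
#' @export
difference_matrix <- function(c1, c2) {
  check_same_grid(c1, c2)
  c1$values <- abs(c1$values - c2$values)
  c1$kind <- "difference"
  c1
}

check_same_grid <- function(c1, c2) {
  if (!identical(dim(c1$values), dim(c2$values)) ||
      !identical(c1$row_bins$chrom[[1]], c2$row_bins$chrom[[1]]) ||
      !identical(c1$resolution, c2$resolution)) {
    abort("matrices are not on the same bin grid.")
  }
  if (!identical(c1$removed_rows, c2$removed_rows)) {
    abort("matrices have different removed-bin masks.")
  }
  invisible(TRUE)
}

#' Classify per-cell correlation changes between two samples
#'
#' Each cell is `"sign_change"` when the correlations have opposite signs
#' (`C1 * C2 < 0`), `"unchanged"` when `|C1 - C2| < tol`, otherwise
#' `"value_change"`.
#'
#' @param c1,c2 Correlation matrices on the same grid.
#' @param tol Equality tolerance for `"unchanged"` (default 1e-9).
#' @return Long tibble with columns `bin_a`, `bin_b`, `c1`, `c2`, `change`.
#' @export
classify_correlation_change <- function(c1, c2, tol = 1e-9) {
  check_same_grid(c1, c2)
  d <- tidy(c1)
  d$c1 <- d$value
  d$c2 <- tidy(c2)$value
  d$value <- NULL
  d$change <- dplyr::case_when(
    abs(d$c1 - d$c2) < tol ~ "unchanged",
    d$c1 * d$c2 < 0 ~ "sign_change",
    .default = "value_change"
  )
  d
}

#' Poisson significance of contact counts
#'
#' Off-diagonal counts of a raw intra-chromosomal matrix are modelled as
#' Poisson with rate `lambda` equal to their mean (diagonal cells, which
#' hold local contacts, are excluded from the rate, as are removed bins).
#' Each cell then gets the probability of observing a *higher* count by
#' chance, `P[i,j] = Pr(X > M[i,j])` with `X ~ Poisson(lambda)`; smaller
#' values mean stronger enrichment.
#'
#' @param m A raw-count intra `contact_matrix`.
#' @return A `contact_matrix` of kind `"significance"` with p-values in
#'   `[0, 1]` and a field `lambda`. Diagonal cells carry p-values too but
#'   did not contribute to `lambda`.
#' @export
poisson_significance <- function(m) {
  stopifnot(inherits(m, "contact_matrix"))
  v <- m$values
  if (nrow(v) != ncol(v)) abort("significance analysis requires a square matrix.")
  keep <- setdiff(seq_len(nrow(v)), m$removed_rows + 1L)
  offdiag <- v[keep, keep, drop = FALSE]
  offdiag <- offdiag[row(offdiag) != col(offdiag)]
  if (length(offdiag) == 0) abort("no off-diagonal cells to estimate lambda.")
  lambda <- mean(offdiag)
  if (lambda == 0) abort("off-diagonal mean is zero; no background to test against.")
  p <- matrix(ppois(v, lambda, lower.tail = FALSE), nrow(v), ncol(v))
  rownames(p) <- rownames(m$values); colnames(p) <- colnames(m$values)
  m$values <- p
  m$kind <- "significance"
  m$lambda <- lambda
  m
}

#' Count inter-chromosomal contacts per chromosome pair
#'
#' @param contacts Contact tibble.
#' @return Tibble `chrom_a`, `chrom_b`, `count` over inter-chromosomal
#'   pairs present in the data.
#' @export
inter_pair_counts <- function(contacts) {
  d <- contacts[contacts$chrom_a != contacts$chrom_b, ]
  dplyr::count(as_tibble(d), .data$chrom_a, .data$chrom_b, name = "count")
}

#' Observed/expected inter-chromosomal contact enrichment
#'
#' For each chromosome pair, the expected contact count is
#' `E_ij = f_i * f_j * N`, where `N` is the total number of
#' inter-chromosomal contacts and `f_i` is the fraction of those contacts
#' with one end on chromosome `i` (so `sum(f) = 2`). The ratio
#' `observed / expected` indicates enrichment (>1) or depletion (<1) of
#' spatial proximity between the two chromosomes.
#'
#' @param pair_counts Tibble `chrom_a`, `chrom_b`, `count` with one row per
#'   unordered chromosome pair (see [inter_pair_counts()]).
#' @return Tibble with columns `chrom_a`, `chrom_b`, `observed`, `f_a`,
#'   `f_b`, `expected`, `ratio`; the fraction table is attached as
#'   attribute `"fractions"`.
#' @examples
#' counts <- tibble::tibble(chrom_a = c("1", "1", "2"),
#'                          chrom_b = c("2", "3", "3"),
#'                          count = c(10, 20, 30))
#' observed_expected_ratios(counts)  # ratio of pair (1,2) is 0.5
#' @export
observed_expected_ratios <- function(pair_counts) {
  d <- as_tibble(pair_counts)
  stopifnot(all(c("chrom_a", "chrom_b", "count") %in% names(d)))
  if (any(d$chrom_a == d$chrom_b)) abort("pair counts must be inter-chromosomal.")
  key <- paste(pmin(d$chrom_a, d$chrom_b), pmax(d$chrom_a, d$chrom_b))
  if (anyDuplicated(key)) abort("duplicate chromosome pairs in `pair_counts`.")
  n_total <- sum(d$count)
  if (n_total == 0) abort("no inter-chromosomal contacts.")
  chroms <- sort(unique(c(d$chrom_a, d$chrom_b)))
  per_chrom <- vapply(chroms, function(ch) {
    sum(d$count[d$chrom_a == ch | d$chrom_b == ch])
  }, 0)
  f <- per_chrom / n_total
  d$f_a <- unname(f[d$chrom_a])
  d$f_b <- unname(f[d$chrom_b])
  d$observed <- d$count
  d$expected <- d$f_a * d$f_b * n_total
  d$ratio <- ifelse(d$expected > 0, d$observed / d$expected, NA_real_)
  d$count <- NULL
  attr(d, "fractions") <- tibble(chrom = chroms, fraction = unname(f))
  d
}

#' Cross-sample Pearson similarity
#'
#' Pearson correlation between per-sample contact-count vectors (for
#' example per-chromosome intra totals, or flattened chromosome-pair inter
#' totals), quantifying global conformation similarity between samples.
#'
#' @param vectors Named list of equal-length numeric vectors, or a data
#'   frame/matrix with one column per sample.
#' @return Tibble with columns `sample_a`, `sample_b`, `r` over all
#'   unordered sample pairs including self-pairs (`r = 1`). Constant
#'   vectors yield `NA` with a warning.
#' @export
cross_sample_correlation <- function(vectors) {
  x <- if (is.data.frame(vectors) || is.matrix(vectors)) {
    as.matrix(vectors)
  } else {
    lens <- lengths(vectors)
    if (length(unique(lens)) != 1) abort("sample vectors must have equal length.")
    do.call(cbind, vectors)
  }
  if (is.null(colnames(x))) colnames(x) <- paste0("sample", seq_len(ncol(x)))
  if (any(apply(x, 2, sd) == 0)) {
    warn("constant sample vector: correlations involving it are undefined (NA).")
  }
  cm <- suppressWarnings(cor(x))
  idx <- which(upper.tri(cm, diag = TRUE), arr.ind = TRUE)
  tibble(
    sample_a = colnames(x)[idx[, 1]],
    sample_b = colnames(x)[idx[, 2]],
    r = cm[idx]
  )
}
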