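#' Bin grid for a chromosome
#'
#' Fixed-resolution, half-open bins `[k*resolution, (k+1)*resolution)` in
#' 0-based coordinates; a 1-based position `p` falls in bin
#' `floor((p-1)/resolution)`. The last bin may be short.
#'
#' @param genome Chromosome-length table.
#' @param resolution Bin size in bp.
#' @param chrom Chromosome to build the grid for.
#' @return Tibble with columns `chrom`, `bin` (0-based index), `start`
#'   (0-based) and `end` (exclusive, clipped to the chromosome length).
#' @export
bin_grid <- function(genome, resolution, chrom) {
  genome <- check_genome(genome)
  stopifnot(resolution > 0)
  len <- genome$length[[chrom_rank(chrom, genome)]]
  n <- ceiling(len / resolution)
  tibble(
    chrom = chrom,
    bin = seq_len(n) - 1L,
    start = (seq_len(n) - 1) * resolution,
    end = pmin(seq_len(n) * resolution, len)
  )
}

#' Construct a contact matrix from plain values
#'
#' Wraps a numeric matrix as a `contact_matrix`, deriving the bin grids
#' from a chromosome name (or pair) and a resolution. Mostly useful for
#' feeding externally computed matrices into the normalization and
#' statistics functions.
#'
#' @param values Non-negative numeric matrix.
#' @param chrom_row Row chromosome name.
#' @param chrom_col Column chromosome name (default: same as `chrom_row`,
#'   i.e. an intra-chromosomal matrix, which must then be square).
#' @param resolution Bin size in bp (default 1).
#' @param kind Matrix kind label (default `"raw_counts"`).
#' @return A `contact_matrix`.
#' @export
contact_matrix <- function(values, chrom_row = "chr1", chrom_col = chrom_row,
                           resolution = 1, kind = "raw_counts") {
  values <- as.matrix(values)
  if (any(values < 0)) abort("contact matrix values must be non-negative.")
  if (chrom_row == chrom_col && nrow(values) != ncol(values)) {
    abort("intra-chromosomal matrices must be square.")
  }
  mk_bins <- function(chrom, n) {
    tibble(chrom = chrom, bin = seq_len(n) - 1L,
           start = (seq_len(n) - 1) * resolution,
           end = seq_len(n) * resolution)
  }
  new_contact_matrix(values, mk_bins(chrom_row, nrow(values)),
                     mk_bins(chrom_col, ncol(values)), resolution, kind)
}

new_contact_matrix <- function(values, row_bins, col_bins, resolution,
                               kind = "raw_counts",
                               removed_rows = integer(), removed_cols = integer(),
                               extra = list()) {
  rownames(values) <- bin_labels(row_bins)
  colnames(values) <- bin_labels(col_bins)
  structure(
    c(list(values = values, row_bins = row_bins, col_bins = col_bins,
           resolution = resolution, kind = kind,
           removed_rows = as.integer(removed_rows),
           removed_cols = as.integer(removed_cols)),
      extra),
    class = "contact_matrix"
  )
}

bin_labels <- function(bins) {
  sprintf("%s:%.0f-%.0f", bins$chrom, bins$start, bins$end)
}

#' @export
print.contact_matrix <- function(x, ...) {
  cat(sprintf(
    "<contact_matrix> %s x %s | %d x %d bins @ %s bp | kind: %s\n",
    x$row_bins$chrom[[1]], x$col_bins$chrom[[1]],
    nrow(x$values), ncol(x$values), format(x$resolution, big.mark = ","),
    x$kind
  ))
  if (length(x$removed_rows) || length(x$removed_cols)) {
    cat(sprintf("removed bins: %d row, %d col\n",
                length(x$removed_rows), length(x$removed_cols)))
  }
  cat(sprintf("total: %g | max: %g\n", sum(x$values), max(x$values)))
  invisible(x)
}

is_intra <- function(m) m$row_bins$chrom[[1]] == m$col_bins$chrom[[1]]

#' Bin contacts into a contact matrix
#'
#' Counts accepted contacts into equal-length bins of one chromosome
#' (intra-chromosomal, symmetric square matrix) or a chromosome pair
#' (inter-chromosomal, rectangular matrix with `chrom_a` on rows). For
#' intra matrices each contact increments both `M[i,j]` and `M[j,i]`;
#' same-bin contacts increment the diagonal once, so the total count over
#' the upper triangle (diagonal included) equals the number of contacts.
#'
#' @param contacts Contact tibble (`chrom_a`, `pos_a`, `chrom_b`, `pos_b`).
#' @param genome Chromosome-length table.
#' @param resolution Bin size in bp.
#' @param chrom_a Row chromosome.
#' @param chrom_b Column chromosome (defaults to `chrom_a`).
#' @return A `contact_matrix` of kind `"raw_counts"`.
#' @examples
#' genome <- tibble::tibble(chrom = "chr1", length = 5e6)
#' contacts <- tibble::tibble(chrom_a = "chr1", pos_a = 1500000L,
#'                            chrom_b = "chr1", pos_b = 3200000L)
#' m <- bin_contacts(contacts, genome, 1e6, "chr1")
#' m$values[2, 4]  # bins 1 and 3 (0-based)
#' @export
bin_contacts <- function(contacts, genome, resolution, chrom_a,
                         chrom_b = chrom_a) {
  genome <- check_genome(genome)
  rg <- bin_grid(genome, resolution, chrom_a)
  cg <- bin_grid(genome, resolution, chrom_b)
  intra <- chrom_a == chrom_b

  sel <- if (intra) {
    contacts$chrom_a == chrom_a & contacts$chrom_b == chrom_a
  } else {
    (contacts$chrom_a == chrom_a & contacts$chrom_b == chrom_b) |
      (contacts$chrom_a == chrom_b & contacts$chrom_b == chrom_a)
  }
  d <- contacts[sel, ]
  la <- genome$length[[chrom_rank(chrom_a, genome)]]
  lb <- genome$length[[chrom_rank(chrom_b, genome)]]
  flip <- d$chrom_a != chrom_a
  pr <- ifelse(flip, d$pos_b, d$pos_a)
  pc <- ifelse(flip, d$pos_a, d$pos_b)
  if (any(pr > la) || any(pc > lb)) {
    abort("contact position beyond chromosome length.")
  }
  i <- floor((pr - 1) / resolution)
  j <- floor((pc - 1) / resolution)
  nr <- nrow(rg); nc <- nrow(cg)
  m <- matrix(0, nr, nc)
  if (length(i)) {
    counts <- tabulate(i * nc + j + 1L, nbins = nr * nc)
    m <- matrix(counts, nr, nc, byrow = TRUE)
  }
  if (intra) {
    m <- m + t(m)
    diag(m) <- diag(m) / 2
  }
  new_contact_matrix(m, rg, cg, resolution)
}

#' Cap matrix values for heat-map rendering
#'
#' Short-range contacts dominate raw counts; capping (default 50) makes
#' long-range structure visible in heat maps. For visualization only —
#' never feed a capped matrix into statistics.
#'
#' @param m A `contact_matrix`.
#' @param cap Maximum displayed value (default 50).
#' @return A `contact_matrix` with values `pmin(value, cap)`.
#' @export
cap_for_visualization <- function(m, cap = 50) {
  stopifnot(inherits(m, "contact_matrix"), cap > 0)
  m$values <- pmin(m$values, cap)
  m$kind <- paste0(m$kind, "_capped")
  m
}

#' Per-bin total contact profile of a chromosome
#'
#' Sums, for each bin of `chrom`, the intra-chromosomal row total plus the
#' row (or column) totals of every inter-chromosomal matrix involving
#' `chrom`, giving the per-region count of intra- plus inter-chromosomal
#' contacts.
#'
#' @param matrices List of `contact_matrix` objects of one sample, all at
#'   the same resolution.
#' @param chrom Chromosome whose profile to compute.
#' @return Tibble with columns `chrom`, `bin`, `start`, `end`, `contacts`.
#' @export
region_contact_profile <- function(matrices, chrom) {
  stopifnot(length(matrices) > 0)
  res <- unique(vapply(matrices, function(m) m$resolution, 0))
  if (length(res) != 1) abort("matrices must share one resolution.")
  grid <- NULL
  total <- NULL
  for (m in matrices) {
    rc <- m$row_bins$chrom[[1]]; cc <- m$col_bins$chrom[[1]]
    v <- if (rc == chrom) {
      rowSums(m$values)
    } else if (cc == chrom) {
      colSums(m$values)
    } else {
      next
    }
    g <- if (rc == chrom) m$row_bins else m$col_bins
    if (is.null(grid)) {
      grid <- g
      total <- numeric(nrow(g))
    } else if (nrow(g) != nrow(grid)) {
      abort("inconsistent bin grids for the requested chromosome.")
    }
    total <- total + v
  }
  if (is.null(grid)) abort(paste0("no matrix involves chromosome ", chrom))
  dplyr::mutate(grid, contacts = unname(total), .keep = "all")
}

#' Turn a contact matrix into a long tibble
#'
#' @param x A `contact_matrix`.
#' @param ... Unused.
#' @return Tibble with one row per cell: `bin_a`, `bin_b` (0-based indices),
#'   `start_a`, `start_b`, `value`.
#' @method tidy contact_matrix
#' @export
tidy.contact_matrix <- function(x, ...) {
  nr <- nrow(x$values); nc <- ncol(x$values)
  tibble(
    bin_a = rep(x$row_bins$bin, times = nc),
    bin_b = rep(x$col_bins$bin, each = nr),
    start_a = rep(x$row_bins$start, times = nc),
    start_b = rep(x$col_bins$start, each = nr),
    value = as.vector(x$values)
  )
}

#' One-row summary of a contact matrix
#'
#' @param x A `contact_matrix`.
#' @param ... Unused.
#' @return Tibble with matrix dimensions, kind, total and removed-bin counts.
#' @method glance contact_matrix
#' @export
glance.contact_matrix <- function(x, ...) {
  tibble(
    chrom_row = x$row_bins$chrom[[1]], chrom_col = x$col_bins$chrom[[1]],
    n_row = nrow(x$values), n_col = ncol(x$values),
    resolution = x$resolution, kind = x$kind,
    total = sum(x$values),
    n_removed = length(x$removed_rows) + length(x$removed_cols) *
      as.integer(!is_intra(x))
  )
}

#' Heat map of a contact matrix
#'
#' @param object A `contact_matrix`.
#' @param cap Optional visualization cap applied before plotting (see
#'   [cap_for_visualization()]); `NULL` for none.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot contact_matrix
#' @export
autoplot.contact_matrix <- function(object, cap = NULL, ...) {
  if (!is.null(cap)) object <- cap_for_visualization(object, cap)
  d <- tidy(object)
  ggplot2::ggplot(d, ggplot2::aes(.data$start_b, .data$start_a,
                                  fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::labs(
      x = object$col_bins$chrom[[1]], y = object$row_bins$chrom[[1]],
      fill = object$kind
    ) +
    ggplot2::coord_fixed()
}

#' Write a contact matrix as TSV with bin labels
#'
#' Row and column names carry the bin coordinates as
#' `chrom:binStart-binEnd`; removed bins are listed in a sidecar file
#' `<path>.removed` when present.
#'
#' @param m A `contact_matrix`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_matrix_tsv <- function(m, path) {
  df <- as.data.frame(m$values)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = TRUE, col.names = NA)
  if (length(m$removed_rows) || length(m$removed_cols)) {
    writeLines(
      c(rownames(m$values)[m$removed_rows + 1L],
        if (!is_intra(m)) colnames(m$values)[m$removed_cols + 1L]),
      paste0(path, ".removed")
    )
  }
  invisible(path)
}

#' Read a contact matrix TSV written by [write_matrix_tsv()]
#'
#' @param path Input path.
#' @param kind Matrix kind to record (default `"raw_counts"`).
#' @return A `contact_matrix`.
#' @export
read_matrix_tsv <- function(path, kind = "raw_counts") {
  df <- utils::read.table(path, sep = "\t", header = TRUE, row.names = 1,
                          check.names = FALSE)
  v <- as.matrix(df)
  parse_bins <- function(labels) {
    parts <- regmatches(labels, regexec("^(.+):([0-9]+)-([0-9]+)$", labels))
    if (any(lengths(parts) != 4)) abort("matrix labels are not chrom:start-end.")
    tibble(
      chrom = vapply(parts, `[[`, "", 2),
      start = as.numeric(vapply(parts, `[[`, "", 3)),
      end = as.numeric(vapply(parts, `[[`, "", 4))
    ) |> dplyr::mutate(bin = dplyr::row_number() - 1L, .after = "chrom")
  }
  rb <- parse_bins(rownames(v)); cb <- parse_bins(colnames(v))
  res <- max(rb$end - rb$start)
  removed <- character()
  sidecar <- paste0(path, ".removed")
  rr <- integer(); rc <- integer()
  if (file.exists(sidecar)) {
    removed <- readLines(sidecar)
    rr <- which(rownames(v) %in% removed) - 1L
    rc <- which(colnames(v) %in% removed) - 1L
  }
  new_contact_matrix(v, rb, cb, res, kind, rr, rc)
}

#' Write a contact matrix in sparse triplet form
#'
#' Three columns `bin_a`, `bin_b`, `value`, non-zero cells only; for intra
#' matrices only the upper triangle (with diagonal) is written.
#'
#' @param m A `contact_matrix`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_matrix_triplets <- function(m, path) {
  d <- tidy(m)
  d <- d[d$value != 0, ]
  if (is_intra(m)) d <- d[d$bin_a <= d$bin_b, ]
  readr::write_tsv(d[c("bin_a", "bin_b", "value")], path, progress = FALSE)
  invisible(path)
}
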