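# Corner-block scan of an inter-chromosomal matrix.
#
# A reciprocal translocation places one segment of each chromosome on a
# shared derivative chromosome, so their inter-chromosomal map gains a
# rectangular corner block of intra-like (dense) contacts; the reciprocal
# derivative enriches the diagonally opposite corner. For each of the four
# corners and every split (a, b) -- a rows x b cols anchored at that
# corner -- the block mean is compared with the mean of the remaining
# cells excluding the opposite corner (which is expected to be enriched
# too for a reciprocal event). Returns the best-scoring corner/split.
scan_corner_blocks <- function(v, row_range = NULL, col_range = NULL) {
  nr <- nrow(v); nc <- ncol(v)
  total <- sum(v)
  ps <- apply(apply(v, 2, cumsum), 1, cumsum)  # ps[j, i] = sum v[1:i, 1:j]
  block_sum <- function(i1, i2, j1, j2) {
    # sum over rows i1:i2, cols j1:j2 via prefix sums (transposed ps)
    s <- function(i, j) if (i < 1 || j < 1) 0 else ps[j, i]
    s(i2, j2) - s(i1 - 1, j2) - s(i2, j1 - 1) + s(i1 - 1, j1 - 1)
  }
  rows <- if (is.null(row_range)) seq_len(nr - 1L) else row_range
  cols <- if (is.null(col_range)) seq_len(nc - 1L) else col_range
  rows <- rows[rows >= 1 & rows < nr]
  cols <- cols[cols >= 1 & cols < nc]
  best <- list(score = -Inf)
  corners <- c("top_left", "top_right", "bottom_left", "bottom_right")
  for (a in rows) {
    for (b in cols) {
      for (corner in corners) {
        bs <- switch(corner,
          top_left = block_sum(1, a, 1, b),
          top_right = block_sum(1, a, b + 1L, nc),
          bottom_left = block_sum(a + 1L, nr, 1, b),
          bottom_right = block_sum(a + 1L, nr, b + 1L, nc)
        )
        os <- switch(corner,  # diagonally opposite corner
          top_left = block_sum(a + 1L, nr, b + 1L, nc),
          top_right = block_sum(a + 1L, nr, 1, b),
          bottom_left = block_sum(1, a, b + 1L, nc),
          bottom_right = block_sum(1, a, 1, b)
        )
        n_block <- switch(corner,
          top_left = a * b,
          top_right = a * (nc - b),
          bottom_left = (nr - a) * b,
          bottom_right = (nr - a) * (nc - b)
        )
        n_opp <- switch(corner,
          top_left = (nr - a) * (nc - b),
          top_right = (nr - a) * b,
          bottom_left = a * (nc - b),
          bottom_right = a * b
        )
        n_rest <- nr * nc - n_block - n_opp
        if (n_rest == 0) next
        rest_mean <- (total - bs - os) / n_rest
        block_mean <- bs / n_block
        score <- if (rest_mean > 0) {
          block_mean / rest_mean
        } else if (block_mean > 0) Inf else 0
        if (score > best$score) {
          best <- list(score = score, corner = corner, a = a, b = b,
                       block_mean = block_mean, rest_mean = rest_mean)
        }
      }
    }
  }
  best
}

#' Detect a reciprocal translocation between two chromosomes
#'
#' Scans the raw inter-chromosomal contact matrix for a corner block with a
#' sudden, drastic excess of contacts (the signature of segments joined on
#' a derivative chromosome), then refines the block boundary by re-binning
#' the contacts at successively finer resolutions within a window of
#' `refine_window` coarse bins around each boundary.
#'
#' The detection statistic is the ratio of the corner-block mean to the
#' mean of the remaining cells, maximized over all four corners and all
#' splits; a call is made when the maximum at the coarsest resolution
#' reaches `enrichment_min`.
#'
#' @param contacts Contact tibble.
#' @param genome Chromosome-length table.
#' @param chrom_a,chrom_b The chromosome pair to test (`chrom_a` on rows).
#' @param resolutions Decreasing bin sizes in bp; detection happens at the
#'   first, refinement at the rest (default 1 Mb, 100 Kb, 10 Kb).
#' @param enrichment_min Minimum corner-block enrichment to call a
#'   translocation (default 5).
#' @param refine_window Half-width, in coarse bins, of the refinement
#'   window around each boundary (default 2).
#' @return A `translocation_model` — a one-row tibble with columns
#'   `chrom_a`, `breakpoint_a`, `chrom_b`, `breakpoint_b` (bp, aligned to
#'   the finest resolution), `orientation` (which ends are exchanged,
#'   e.g. `"head_a-tail_b"`), `score` and `resolution` — or `NULL` when no
#'   corner reaches `enrichment_min`.
#' @export
detect_translocation <- function(contacts, genome, chrom_a, chrom_b,
                                 resolutions = c(1e6, 1e5, 1e4),
                                 enrichment_min = 5, refine_window = 2L) {
  genome <- check_genome(genome)
  stopifnot(length(resolutions) >= 1, all(diff(resolutions) < 0))
  m <- bin_contacts(contacts, genome, resolutions[[1]], chrom_a, chrom_b)
  if (nrow(m$values) < 4 || ncol(m$values) < 4) {
    abort("inter matrix too small (< 4 bins a side) for detection.")
  }
  best <- scan_corner_blocks(m$values)
  if (best$score < enrichment_min) return(NULL)

  res <- resolutions[[1]]
  # boundary expressed as bp at the split between block and rest
  bp_a <- best$a * res
  bp_b <- best$b * res
  for (fres in resolutions[-1]) {
    mf <- bin_contacts(contacts, genome, fres, chrom_a, chrom_b)
    win <- refine_window * res / fres
    ca <- bp_a / fres; cb <- bp_b / fres
    rows <- seq(floor(ca - win), ceiling(ca + win))
    cols <- seq(floor(cb - win), ceiling(cb + win))
    ref <- scan_corner_blocks(mf$values, row_range = rows, col_range = cols)
    if (ref$score > -Inf) {
      bp_a <- ref$a * fres
      bp_b <- ref$b * fres
      best$corner <- ref$corner
    }
    res <- fres
  }
  orientation <- switch(best$corner,
    top_left = "head_a-head_b",
    top_right = "head_a-tail_b",
    bottom_left = "tail_a-head_b",
    bottom_right = "tail_a-tail_b"
  )
  structure(
    tibble(chrom_a = chrom_a, breakpoint_a = bp_a,
           chrom_b = chrom_b, breakpoint_b = bp_b,
           orientation = orientation, score = best$score,
           resolution = res),
    class = c("translocation_model", "tbl_df", "tbl", "data.frame")
  )
}

#' @export
print.translocation_model <- function(x, ...) {
  cat(sprintf(
    "<translocation_model> t(%s;%s) breakpoints %s:%.0f / %s:%.0f (%s), score %.1f @ %g bp\n",
    x$chrom_a, x$chrom_b, x$chrom_a, x$breakpoint_a, x$chrom_b,
    x$breakpoint_b, x$orientation, x$score, x$resolution
  ))
  invisible(x)
}

#' Build a translocation model by hand
#'
#' @param chrom_a,chrom_b Chromosome names.
#' @param breakpoint_a,breakpoint_b Breakpoints in bp.
#' @param orientation Which ends are exchanged: `"head_a-head_b"`,
#'   `"head_a-tail_b"`, `"tail_a-head_b"` or `"tail_a-tail_b"`, where
#'   `head`/`tail` name the translocated segment of each chromosome
#'   (before/after its breakpoint).
#' @return A `translocation_model`.
#' @export
translocation_model <- function(chrom_a, breakpoint_a, chrom_b, breakpoint_b,
                                orientation = "head_a-tail_b") {
  stopifnot(orientation %in% c("head_a-head_b", "head_a-tail_b",
                               "tail_a-head_b", "tail_a-tail_b"))
  structure(
    tibble(chrom_a = chrom_a, breakpoint_a = breakpoint_a,
           chrom_b = chrom_b, breakpoint_b = breakpoint_b,
           orientation = orientation, score = NA_real_,
           resolution = NA_real_),
    class = c("translocation_model", "tbl_df", "tbl", "data.frame")
  )
}

#' Partition an inter-chromosomal matrix around a translocation
#'
#' Splits every cell of the inter matrix into four regions: `A` =
#' non-translocated x non-translocated, `B` = translocated x translocated
#' (the dense derivative-chromosome block), `C` = non-translocated rows x
#' translocated columns, `D` = translocated rows x non-translocated
#' columns.
#'
#' @param m The inter-chromosomal `contact_matrix` (rows = `chrom_a`).
#' @param model A `translocation_model` whose breakpoints lie within the
#'   matrix extent.
#' @return A character matrix of the same dimensions with entries
#'   `"A"`, `"B"`, `"C"`, `"D"`.
#' @export
partition_regions <- function(m, model) {
  stopifnot(inherits(m, "contact_matrix"))
  res <- m$resolution
  nr <- nrow(m$values); nc <- ncol(m$values)
  ka <- round(model$breakpoint_a / res)
  kb <- round(model$breakpoint_b / res)
  if (ka < 0 || ka > nr || kb < 0 || kb > nc) {
    abort("breakpoints outside the matrix extent.")
  }
  parts <- strsplit(model$orientation, "-")[[1]]
  trans_rows <- if (parts[[1]] == "head_a") seq_len(ka) else
    seq_len(nr)[seq_len(nr) > ka]
  trans_cols <- if (parts[[2]] == "head_b") seq_len(kb) else
    seq_len(nc)[seq_len(nc) > kb]
  in_tr <- matrix(FALSE, nr, nc); in_tr[trans_rows, ] <- TRUE
  in_tc <- matrix(FALSE, nr, nc); in_tc[, trans_cols] <- TRUE
  out <- matrix("A", nr, nc)
  out[in_tr & in_tc] <- "B"
  out[!in_tr & in_tc] <- "C"
  out[in_tr & !in_tc] <- "D"
  out
}

#' Correct an inter-chromosomal matrix for a translocation
#'
#' Reconstructs the underlying spatial (non-rearrangement) contact signal
#' of a translocated chromosome pair, keeping reference-genome
#' coordinates. Counts in regions `A` and `B` are halved; each region-`C`
#' cell `(i, j)` becomes `max(0, value - mean of row i within region A)`;
#' each region-`D` cell `(i, j)` becomes `max(0, value - mean of column j
#' within region A)`.
#'
#' @param m The raw inter-chromosomal `contact_matrix`.
#' @param partition Character region matrix from [partition_regions()].
#' @return A `contact_matrix` of kind `"corrected"`, non-negative
#'   everywhere.
#' @export
reconstruct_corrected_matrix <- function(m, partition) {
  stopifnot(inherits(m, "contact_matrix"),
            identical(dim(partition), dim(m$values)))
  v <- m$values
  out <- v
  a_mask <- partition == "A"
  if ((any(partition == "C") || any(partition == "D")) && !any(a_mask)) {
    abort("region A is empty; no background available to subtract.")
  }
  out[a_mask] <- v[a_mask] / 2
  out[partition == "B"] <- v[partition == "B"] / 2
  row_bg <- vapply(seq_len(nrow(v)), function(i) {
    cells <- v[i, ][a_mask[i, ]]
    if (length(cells)) mean(cells) else NA_real_
  }, 0)
  col_bg <- vapply(seq_len(ncol(v)), function(j) {
    cells <- v[, j][a_mask[, j]]
    if (length(cells)) mean(cells) else NA_real_
  }, 0)
  c_idx <- which(partition == "C", arr.ind = TRUE)
  if (nrow(c_idx)) {
    bg <- row_bg[c_idx[, 1]]
    if (anyNA(bg)) abort("a region-C row has no region-A cells.")
    out[c_idx] <- pmax(0, v[c_idx] - bg)
  }
  d_idx <- which(partition == "D", arr.ind = TRUE)
  if (nrow(d_idx)) {
    bg <- col_bg[d_idx[, 2]]
    if (anyNA(bg)) abort("a region-D column has no region-A cells.")
    out[d_idx] <- pmax(0, v[d_idx] - bg)
  }
  m$values <- out
  m$kind <- "corrected"
  m
}
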