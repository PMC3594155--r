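#' Read a mapped read-pair table
#'
#' Reads paired-end mapping candidates from one of two tab-separated
#' dialects:
#'
#' * **full**: one line per read pair:
#'   `read_id, n1, (chrom, pos, strand) x n1, n2, (chrom, pos, strand) x n2,
#'   read_length`, where `n1`/`n2` are the number of candidate mapping
#'   locations of each end. This dialect carries multi-mapping ambiguity.
#' * **simple**: five columns `read_id, chrom1, pos1, chrom2, pos2` for data
#'   that is already uniquely mapped (strand recorded as `+`, read length
#'   as `read_length`).
#'
#' The dialect is detected from the first line unless given explicitly.
#'
#' @param path Path to the pair table.
#' @param dialect `"auto"` (default), `"full"` or `"simple"`.
#' @param read_length Read length assumed for the simple dialect (bp).
#' @return A tibble of mapping candidates in long form, one row per
#'   candidate location, with columns `read_id`, `end` (1 or 2), `cand`
#'   (candidate index within the end), `chrom`, `pos` (1-based), `strand`
#'   and `read_length`.
#' @seealso [write_pairs()], [filter_pairs()]
#' @export
read_pairs <- function(path, dialect = c("auto", "full", "simple"),
                       read_length = 100L) {
  dialect <- match.arg(dialect)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) {
    return(empty_pairs())
  }
  if (dialect == "auto") {
    tok <- strsplit(lines[[1]], "\t", fixed = TRUE)[[1]]
    dialect <- if (length(tok) == 5 && is.na(suppressWarnings(as.numeric(tok[[2]])))) {
      "simple"
    } else {
      "full"
    }
  }
  if (dialect == "simple") {
    d <- readr::read_tsv(
      I(lines),
      col_names = c("read_id", "chrom1", "pos1", "chrom2", "pos2"),
      col_types = "ccici", progress = FALSE
    )
    return(tibble(
      read_id = rep(d$read_id, 2),
      end = rep(c(1L, 2L), each = nrow(d)),
      cand = 1L,
      chrom = c(d$chrom1, d$chrom2),
      pos = c(d$pos1, d$pos2),
      strand = "+",
      read_length = as.integer(read_length)
    ) |> dplyr::arrange(match(.data$read_id, d$read_id), .data$end))
  }
  parse_full_dialect(lines)
}

empty_pairs <- function() {
  tibble(
    read_id = character(), end = integer(), cand = integer(),
    chrom = character(), pos = integer(), strand = character(),
    read_length = integer()
  )
}

parse_full_dialect <- function(lines) {
  toks <- strsplit(lines, "\t", fixed = TRUE)
  nt <- lengths(toks)
  n1 <- suppressWarnings(as.integer(vapply(toks, function(t)
    if (length(t) >= 2L) t[[2L]] else NA_character_, "")))
  bad <- which(is.na(n1) | n1 < 0L | nt < 4L + 3L * pmax(n1, 0L))
  if (length(bad) == 0) {
    n2 <- suppressWarnings(as.integer(mapply(function(t, k) t[[3L + 3L * k]],
                                             toks, n1)))
    bad <- which(is.na(n2) | nt != 4L + 3L * (n1 + n2))
  }
  if (length(bad) > 0) {
    abort(paste0("malformed pair-table line ", bad[[1]], ": ", lines[[bad[[1]]]]))
  }
  n2 <- as.integer(mapply(function(t, k) t[[3L + 3L * k]], toks, n1))
  flat <- unlist(toks, use.names = FALSE)
  offs <- cumsum(c(0L, head(nt, -1L)))
  ids <- flat[offs + 1L]
  rl <- as.integer(flat[offs + nt])
  # positions of the candidate triplets within each line
  per_line <- function(n, start_off) {
    idx <- sequence(n)  # 1..n per line
    line <- rep(seq_along(n), n)
    base <- offs[line] + start_off[line] + (idx - 1L) * 3L
    list(line = line, cand = idx, base = base)
  }
  e1 <- per_line(n1, rep(2L, length(n1)))
  e2 <- per_line(n2, 3L + 3L * n1)
  build <- function(e, end) {
    tibble(
      read_id = ids[e$line],
      end = end,
      cand = e$cand,
      chrom = flat[e$base + 1L],
      pos = as.integer(flat[e$base + 2L]),
      strand = flat[e$base + 3L],
      read_length = rl[e$line],
      .line = e$line
    )
  }
  out <- dplyr::bind_rows(build(e1, 1L), build(e2, 2L))
  out <- dplyr::arrange(out, .data$.line, .data$end, .data$cand)
  out$.line <- NULL
  out
}

#' Write a read-pair table
#'
#' @param pairs Long-form candidate tibble as returned by [read_pairs()] or
#'   [simulate_pairs()].
#' @param path Output path.
#' @param dialect `"full"` (default; round-trips multi-mapping candidates) or
#'   `"simple"` (five columns; requires uniquely mapped pairs).
#' @return `path`, invisibly.
#' @export
write_pairs <- function(pairs, path, dialect = c("full", "simple")) {
  dialect <- match.arg(dialect)
  ids <- unique(pairs$read_id)
  if (dialect == "simple") {
    n <- dplyr::count(pairs, .data$read_id, .data$end)
    if (any(n$n != 1L)) {
      abort("simple dialect requires exactly one candidate per end.")
    }
    w <- tidyr::pivot_wider(
      pairs[c("read_id", "end", "chrom", "pos")],
      names_from = "end", values_from = c("chrom", "pos")
    )
    w <- w[match(ids, w$read_id), ]
    readr::write_tsv(w[c("read_id", "chrom_1", "pos_1", "chrom_2", "pos_2")],
                     path, col_names = FALSE, progress = FALSE)
    return(invisible(path))
  }
  sp <- split(pairs, factor(pairs$read_id, levels = ids))
  lines <- vapply(sp, function(d) {
    fmt_end <- function(e) {
      dd <- d[d$end == e, , drop = FALSE]
      c(nrow(dd), rbind(dd$chrom, dd$pos, dd$strand))
    }
    paste(c(d$read_id[[1]], fmt_end(1L), fmt_end(2L), d$read_length[[1]]),
          collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' Read a chromosome-length table
#'
#' Two-column TSV (`chrom`, `length` in bp). The row order defines the
#' canonical chromosome order used when orienting contacts.
#'
#' @param path Path to the table.
#' @return A tibble with columns `chrom` and `length`.
#' @export
read_genome <- function(path) {
  g <- readr::read_tsv(path, col_names = c("chrom", "length"),
                       col_types = "cd", progress = FALSE)
  check_genome(g)
}

#' Classify mapped read pairs into contacts
#'
#' Applies one of two strategies for resolving multi-mapping candidates of
#' paired-end reads:
#'
#' * `strict_unique` (default): a pair is accepted only when **both** ends
#'   map to exactly one location; any end with two or more candidates is
#'   discarded as multi-mapped.
#' * `four_case`: the four-case protocol. Case 1: both ends unique. Cases
#'   2/3: one end unique, the other with two candidates; the pair is valid
#'   when one of the two candidates lies within `insert_length` of the
#'   unique end (that nearby candidate is taken as the physically linked
#'   insert end, and the *other* candidate becomes the contact partner).
#'   Case 4: both ends with two candidates `A,B` / `C,D`; valid when
#'   `|A-C| < read_length` and `|B-D| < read_length`, in which case the
#'   contact `(A, C)` is emitted. Any end with three or more candidates is
#'   discarded under either strategy.
#'
#' Accepted contacts are emitted in canonical order: ends sorted by the
#' chromosome order of `genome`, then by position.
#'
#' @param pairs Long-form candidate tibble (see [read_pairs()]).
#' @param genome Chromosome-length table (see [read_genome()]).
#' @param strategy `"strict_unique"` or `"four_case"`.
#' @param insert_length Maximum distance (bp) between the unique end and a
#'   candidate of the ambiguous end for cases 2/3; the expected DNA insert
#'   length (default 2000).
#' @return One row per input read pair with columns `read_id`, `status`
#'   (`"accepted"`, `"unmapped"`, `"multi_mapped"` or `"invalid_case"`) and,
#'   for accepted pairs, the contact coordinates `chrom_a`, `pos_a`,
#'   `chrom_b`, `pos_b`.
#' @export
classify_pairs <- function(pairs, genome,
                           strategy = c("strict_unique", "four_case"),
                           insert_length = 2000) {
  strategy <- match.arg(strategy)
  genome <- check_genome(genome)
  stopifnot(insert_length > 0)
  ids <- unique(pairs$read_id)
  if (length(ids) == 0) {
    return(tibble(read_id = character(), status = character(),
                  chrom_a = character(), pos_a = integer(),
                  chrom_b = character(), pos_b = integer()))
  }
  chrom_rank(unique(pairs$chrom), genome)  # validates chromosome names
  if (any(pairs$pos < 1L)) abort("candidate positions must be >= 1.")

  cnt <- dplyr::count(pairs, .data$read_id, .data$end)
  cnt <- tidyr::pivot_wider(cnt, names_from = "end", values_from = "n",
                            names_prefix = "n", values_fill = 0L)
  if (!"n1" %in% names(cnt)) cnt$n1 <- 0L
  if (!"n2" %in% names(cnt)) cnt$n2 <- 0L
  cnt <- cnt[match(ids, cnt$read_id), ]

  max_cand <- if (strategy == "strict_unique") 1L else 2L
  status <- rep("accepted", length(ids))
  status[cnt$n1 == 0L | cnt$n2 == 0L] <- "unmapped"
  mm <- cnt$n1 > max_cand | cnt$n2 > max_cand
  status[mm & status == "accepted"] <- "multi_mapped"

  # wide candidate coordinates for candidates 1 and 2 of each end
  w <- pairs[pairs$cand <= 2L, c("read_id", "end", "cand", "chrom", "pos")]
  w <- tidyr::pivot_wider(w, names_from = c("end", "cand"),
                          values_from = c("chrom", "pos"), names_sep = "_")
  for (col in c("chrom_1_1", "chrom_1_2", "chrom_2_1", "chrom_2_2")) {
    if (!col %in% names(w)) w[[col]] <- NA_character_
  }
  for (col in c("pos_1_1", "pos_1_2", "pos_2_1", "pos_2_2")) {
    if (!col %in% names(w)) w[[col]] <- NA_integer_
  }
  w <- w[match(ids, w$read_id), ]
  rl <- pairs$read_length[match(ids, pairs$read_id)]

  ca <- w$chrom_1_1; pa <- w$pos_1_1
  cb <- w$chrom_2_1; pb <- w$pos_2_1

  if (strategy == "four_case") {
    dist_or_inf <- function(c1, p1, c2, p2) {
      d <- abs(p1 - p2)
      d[is.na(c1) | is.na(c2) | c1 != c2] <- Inf
      d
    }
    amb2 <- status == "accepted" & cnt$n1 == 1L & cnt$n2 == 2L
    amb3 <- status == "accepted" & cnt$n1 == 2L & cnt$n2 == 1L
    amb4 <- status == "accepted" & cnt$n1 == 2L & cnt$n2 == 2L

    # cases 2/3: candidate of the ambiguous end nearest the unique end is the
    # insert mate; the other candidate is the contact partner
    resolve23 <- function(sel, uc, up, c1, p1, c2, p2) {
      d1 <- dist_or_inf(uc, up, c1, p1)
      d2 <- dist_or_inf(uc, up, c2, p2)
      valid <- pmin(d1, d2) <= insert_length
      take2 <- d1 <= d2  # candidate 1 is the mate -> partner is candidate 2
      list(valid = valid & sel,
           pc = ifelse(take2, c2, c1), pp = ifelse(take2, p2, p1))
    }
    r2 <- resolve23(amb2, ca, pa, w$chrom_2_1, w$pos_2_1, w$chrom_2_2, w$pos_2_2)
    status[amb2 & !r2$valid] <- "invalid_case"
    cb[r2$valid] <- r2$pc[r2$valid]; pb[r2$valid] <- r2$pp[r2$valid]

    r3 <- resolve23(amb3, cb, pb, w$chrom_1_1, w$pos_1_1, w$chrom_1_2, w$pos_1_2)
    status[amb3 & !r3$valid] <- "invalid_case"
    ca[r3$valid] <- r3$pc[r3$valid]; pa[r3$valid] <- r3$pp[r3$valid]

    dac <- dist_or_inf(w$chrom_1_1, w$pos_1_1, w$chrom_2_1, w$pos_2_1)
    dbd <- dist_or_inf(w$chrom_1_2, w$pos_1_2, w$chrom_2_2, w$pos_2_2)
    ok4 <- dac < rl & dbd < rl
    status[amb4 & !ok4] <- "invalid_case"
    # case 4 emits (A, C), already in ca/pa/cb/pb
  }

  acc <- status == "accepted"
  out <- tibble(read_id = ids, status = status,
                chrom_a = ifelse(acc, ca, NA_character_),
                pos_a = ifelse(acc, pa, NA_integer_),
                chrom_b = ifelse(acc, cb, NA_character_),
                pos_b = ifelse(acc, pb, NA_integer_))
  canonicalize_contacts(out, genome)
}

# Order each accepted contact's two ends by chromosome rank then position.
canonicalize_contacts <- function(x, genome) {
  acc <- !is.na(x$chrom_a) & !is.na(x$chrom_b)
  ra <- rep(NA_integer_, nrow(x)); rb <- ra
  ra[acc] <- chrom_rank(x$chrom_a[acc], genome)
  rb[acc] <- chrom_rank(x$chrom_b[acc], genome)
  swap <- acc & (ra > rb | (ra == rb & x$pos_a > x$pos_b))
  swap[is.na(swap)] <- FALSE
  if (any(swap)) {
    tmp_c <- x$chrom_a[swap]; tmp_p <- x$pos_a[swap]
    x$chrom_a[swap] <- x$chrom_b[swap]; x$pos_a[swap] <- x$pos_b[swap]
    x$chrom_b[swap] <- tmp_c; x$pos_b[swap] <- tmp_p
  }
  x
}

#' Test contacts against the minimum intra-chromosomal separation
#'
#' A contact passes when its ends are on different chromosomes or at least
#' `min_separation` bp apart on the same chromosome.
#'
#' @param contacts Tibble with columns `chrom_a`, `pos_a`, `chrom_b`, `pos_b`.
#' @param min_separation Minimum same-chromosome separation in bp
#'   (default 2000).
#' @return Logical vector, one element per contact.
#' @export
apply_separation_filter <- function(contacts, min_separation = 2000) {
  stopifnot(min_separation >= 0)
  contacts$chrom_a != contacts$chrom_b |
    abs(contacts$pos_b - contacts$pos_a) >= min_separation
}

#' Filter a read-pair table into accepted contacts
#'
#' Runs [classify_pairs()] and then the same-chromosome separation filter,
#' returning the accepted contacts together with per-reason rejection
#' counts. Every input read pair is counted exactly once, either as
#' accepted or under one rejection reason.
#'
#' @inheritParams classify_pairs
#' @param min_separation Minimum same-chromosome separation in bp
#'   (default 2000).
#' @param dedup Collapse duplicate identical contacts (default `FALSE`;
#'   duplicates are kept).
#' @return A tibble of contacts (`chrom_a`, `pos_a`, `chrom_b`, `pos_b`) in
#'   canonical order, with the counts attached as attribute `"stats"`
#'   (retrieve with [filter_stats()]).
#' @examples
#' genome <- tibble::tibble(chrom = c("chr1", "chr2"), length = 5e6)
#' pairs <- tibble::tibble(
#'   read_id = rep(c("r1", "r2"), each = 2), end = rep(1:2, 2), cand = 1L,
#'   chrom = c("chr1", "chr1", "chr1", "chr2"),
#'   pos = c(100000L, 105000L, 1000L, 1000L),
#'   strand = "+", read_length = 100L
#' )
#' contacts <- filter_pairs(pairs, genome)
#' filter_stats(contacts)
#' @export
filter_pairs <- function(pairs, genome,
                         strategy = c("strict_unique", "four_case"),
                         min_separation = 2000, insert_length = 2000,
                         dedup = FALSE) {
  cls <- classify_pairs(pairs, genome, strategy, insert_length)
  acc <- cls[cls$status == "accepted", ]
  keep <- apply_separation_filter(acc, min_separation)
  contacts <- acc[keep, c("chrom_a", "pos_a", "chrom_b", "pos_b")]
  if (dedup) contacts <- dplyr::distinct(contacts)
  reasons <- c("multi_mapped", "unmapped", "invalid_case")
  stats <- tibble(
    reason = c("accepted", reasons, "short_separation"),
    n = unname(c(sum(keep),
                 vapply(reasons, function(r) sum(cls$status == r), 0L),
                 sum(!keep)))
  )
  attr(contacts, "stats") <- stats
  class(contacts) <- c("hic_contacts", class(contacts))
  contacts
}

#' Retrieve the filtering statistics attached to a contact table
#'
#' @param contacts Result of [filter_pairs()].
#' @return Tibble with columns `reason` and `n`.
#' @export
filter_stats <- function(contacts) {
  s <- attr(contacts, "stats")
  if (is.null(s)) abort("no filtering statistics attached to this object.")
  s
}

#' @export
print.hic_contacts <- function(x, ...) {
  s <- attr(x, "stats")
  cat("<hic_contacts> ", nrow(x), " accepted contacts\n", sep = "")
  if (!is.null(s)) {
    rej <- s[s$reason != "accepted" & s$n > 0, ]
    if (nrow(rej) > 0) {
      cat("rejected:", paste0(rej$reason, "=", rej$n, collapse = ", "), "\n")
    }
  }
  NextMethod()
}

#' Write accepted contacts as a four-column TSV
#'
#' @param contacts Contact tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_contacts <- function(contacts, path) {
  readr::write_tsv(as_tibble(contacts)[c("chrom_a", "pos_a", "chrom_b", "pos_b")],
                   path, progress = FALSE)
  invisible(path)
}

#' Read a four-column contact TSV written by [write_contacts()]
#'
#' @param path Input path.
#' @return Contact tibble.
#' @export
read_contacts <- function(path) {
  readr::read_tsv(path, col_types = "cici", progress = FALSE)
}
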