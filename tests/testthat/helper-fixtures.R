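# Shared fixture builders. Everything is generated in code; no data files.

two_chrom_genome <- function(len = 5e6) {
  tibble::tibble(chrom = c("chr1", "chr2"), length = len)
}

# Build a long-form candidate table from a compact spec:
# each record is list(id, end1 = list(c(chrom, pos), ...), end2 = ..., rl)
make_pairs <- function(records, read_length = 100L) {
  rows <- lapply(records, function(r) {
    mk <- function(cands, end) {
      if (length(cands) == 0) return(NULL)
      tibble::tibble(
        read_id = r$id, end = end, cand = seq_along(cands),
        chrom = vapply(cands, function(x) as.character(x[[1]]), ""),
        pos = vapply(cands, function(x) as.integer(x[[2]]), 0L),
        strand = "+", read_length = as.integer(r$rl %||% read_length)
      )
    }
    dplyr::bind_rows(mk(r$end1, 1L), mk(r$end2, 2L))
  })
  empty <- tibble::tibble(
    read_id = character(), end = integer(), cand = integer(),
    chrom = character(), pos = integer(), strand = character(),
    read_length = integer()
  )
  dplyr::bind_rows(c(list(empty), rows))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Uniquely mapped pair shorthand
unique_pair <- function(id, chrom1, pos1, chrom2, pos2) {
  list(id = id, end1 = list(c(chrom1, pos1)), end2 = list(c(chrom2, pos2)))
}

# Random symmetric non-negative matrix with positive row sums
random_symmetric <- function(n, seed) {
  withr::with_seed(seed, {
    m <- matrix(stats::runif(n * n, 0.5, 5), n, n)
    (m + t(m)) / 2
  })
}

# Independent SCN reference: plain loop, no shared code with the package
scn_reference <- function(v, iters = 500, tol = 1e-10) {
  for (i in seq_len(iters)) {
    for (j in seq_len(ncol(v))) {
      nj <- sqrt(sum(v[, j]^2)); if (nj > 0) v[, j] <- v[, j] / nj
    }
    for (i2 in seq_len(nrow(v))) {
      ni <- sqrt(sum(v[i2, ]^2)); if (ni > 0) v[i2, ] <- v[i2, ] / ni
    }
    if (max(abs(v - t(v))) < tol) break
  }
  v
}

# Build an interaction network directly from an edge list matrix/data frame
edges_to_network <- function(edges) {
  counts <- tibble::tibble(
    id_a = as.character(edges[, 1]), id_b = as.character(edges[, 2]),
    kind_a = "GENE", kind_b = "GENE",
    count = if (ncol(edges) >= 3) as.numeric(edges[, 3]) else 1
  )
  build_network(counts, threshold = 0)
}

# Compare every graph statistic of `net` with independent igraph-based
# oracles (distances, geodesic enumeration, neighbor-set arithmetic).
expect_network_matches_oracles <- function(net) {
  g <- igraph::graph_from_data_frame(
    net$edges[c("id_a", "id_b")], directed = FALSE, vertices = net$nodes$id
  )
  ids <- net$nodes$id
  D <- igraph::distances(g)[ids, ids]

  ref_deg <- table(igraph::degree(g))
  dh <- degree_histogram(net)
  testthat::expect_equal(dh$degree, as.integer(names(ref_deg)))
  testthat::expect_equal(dh$n_nodes, as.integer(ref_deg))
  testthat::expect_equal(sum(igraph::degree(g)), 2 * nrow(net$edges))

  dv <- D[upper.tri(D)]
  dv <- dv[is.finite(dv) & dv > 0]
  sp <- shortest_path_histogram(net)
  testthat::expect_equal(sp$n_pairs, as.integer(table(dv)),
                         ignore_attr = TRUE)

  cc <- clustering_coefficient(net)$clustering
  ref_cc <- unname(igraph::transitivity(g, type = "localundirected",
                                        isolates = "zero"))
  testthat::expect_equal(cc, ref_cc, tolerance = 1e-12)

  cl <- closeness_centrality(net)$closeness
  ref_cl <- vapply(seq_along(ids), function(i) {
    d <- D[i, ]; d <- d[is.finite(d) & d > 0]
    if (length(d) == 0) 0 else 1 / mean(d)
  }, 0)
  testthat::expect_equal(cl, ref_cl, tolerance = 1e-12)

  st <- stress_distribution(net)$stress$stress
  ref_st <- numeric(length(ids))
  for (src in seq_along(ids)) {
    asp <- igraph::all_shortest_paths(g, from = src)
    geo <- asp$vpaths %||% asp$res
    for (pth in geo) {
      iv <- as.integer(pth)
      if (length(iv) > 2) {
        mid <- iv[-c(1, length(iv))]
        ref_st[mid] <- ref_st[mid] + 1
      }
    }
  }
  testthat::expect_equal(st, ref_st / 2, tolerance = 1e-12)

  tc <- topological_coefficient(net)$topological_coefficient
  nbrs <- lapply(seq_along(ids), function(i)
    as.integer(igraph::neighbors(g, i)))
  ref_tc <- vapply(seq_along(ids), function(i) {
    k <- length(nbrs[[i]])
    if (k <= 1) return(0)
    js <- c()
    for (mm in seq_along(ids)) {
      if (mm == i) next
      shared <- length(intersect(nbrs[[i]], nbrs[[mm]]))
      direct <- mm %in% nbrs[[i]]
      if (shared > 0 || direct) js <- c(js, shared + direct)
    }
    if (length(js) == 0) 0 else mean(js) / k
  }, 0)
  testthat::expect_equal(tc, ref_tc, tolerance = 1e-12)
  invisible(TRUE)
}

# Random connected-ish simple graph on n nodes
random_network <- function(n, p, seed) {
  withr::with_seed(seed, {
    pairs <- t(utils::combn(n, 2))
    keep <- stats::runif(nrow(pairs)) < p
    e <- pairs[keep, , drop = FALSE]
    if (nrow(e) == 0) e <- pairs[1, , drop = FALSE]
    edges_to_network(cbind(sprintf("n%02d", e[, 1]), sprintf("n%02d", e[, 2]),
                           sample(1:5, nrow(e), replace = TRUE)))
  })
}
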