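#' Read a feature-annotation table
#'
#' Accepts a five-column TSV `id, chrom, start, end, kind` (1-based
#' inclusive coordinates) or BED (`chrom, start, end, name, kind`; 0-based
#' half-open, converted on read).
#'
#' @param path Path to the annotation file.
#' @param format `"auto"` (default), `"tsv"` or `"bed"`.
#' @return Tibble with columns `id`, `chrom`, `start`, `end`, `kind`.
#' @export
read_features <- function(path, format = c("auto", "tsv", "bed")) {
  format <- match.arg(format)
  first <- strsplit(readLines(path, n = 1), "\t", fixed = TRUE)[[1]]
  if (format == "auto") {
    format <- if (!is.na(suppressWarnings(as.numeric(first[[2]])))) "bed" else "tsv"
  }
  if (format == "bed") {
    d <- readr::read_tsv(path, col_names = c("chrom", "start", "end", "id", "kind"),
                         col_types = "ciicc", progress = FALSE)
    d$start <- d$start + 1L  # BED is 0-based half-open
    return(d[c("id", "chrom", "start", "end", "kind")])
  }
  readr::read_tsv(path, col_names = c("id", "chrom", "start", "end", "kind"),
                  col_types = "cciic", progress = FALSE)
}

#' Count contacts between pairs of genomic features
#'
#' Matches each contact end to every feature of an allowed kind containing
#' its position (1-based inclusive containment) and increments the count of
#' every cross pair of distinct features, one from each end. Ends matching
#' no feature contribute nothing; self-pairs (both ends in the same
#' feature) are dropped. Only `"GENE"` entries are used by default;
#' pseudogenes, RNAs, CDS and UTR records are excluded unless requested.
#'
#' @param contacts Contact tibble.
#' @param features Feature tibble (see [read_features()]).
#' @param node_kinds Feature kinds allowed as network nodes
#'   (default `"GENE"`).
#' @return Tibble `id_a`, `id_b`, `kind_a`, `kind_b`, `count` with
#'   `id_a < id_b`, one row per unordered feature pair in contact.
#' @export
map_contacts_to_features <- function(contacts, features, node_kinds = "GENE") {
  stopifnot(all(features$start <= features$end))
  f <- as_tibble(features)[features$kind %in% node_kinds, ]
  empty <- tibble(id_a = character(), id_b = character(),
                  kind_a = character(), kind_b = character(),
                  count = integer())
  if (nrow(f) == 0 || nrow(contacts) == 0) return(empty)

  match_end <- function(chrom, pos) {
    hits <- vector("list", length(unique(chrom)))
    out <- list()
    for (ch in unique(chrom)) {
      fi <- which(f$chrom == ch)
      ci <- which(chrom == ch)
      if (length(fi) == 0 || length(ci) == 0) next
      ov <- IRanges::findOverlaps(
        IRanges::IRanges(pos[ci], width = 1L),
        IRanges::IRanges(f$start[fi], f$end[fi])
      )
      out[[ch]] <- tibble(
        contact = ci[S4Vectors::queryHits(ov)],
        feature = fi[S4Vectors::subjectHits(ov)]
      )
    }
    dplyr::bind_rows(out)
  }
  m1 <- match_end(contacts$chrom_a, contacts$pos_a)
  m2 <- match_end(contacts$chrom_b, contacts$pos_b)
  if (nrow(m1) == 0 || nrow(m2) == 0) return(empty)
  pairs <- dplyr::inner_join(m1, m2, by = "contact",
                             relationship = "many-to-many")
  pairs <- pairs[pairs$feature.x != pairs$feature.y, ]
  if (nrow(pairs) == 0) return(empty)
  ia <- pmin(pairs$feature.x, pairs$feature.y)
  ib <- pmax(pairs$feature.x, pairs$feature.y)
  counted <- dplyr::count(tibble(ia = ia, ib = ib), .data$ia, .data$ib,
                          name = "count")
  out <- tibble(
    id_a = f$id[counted$ia], id_b = f$id[counted$ib],
    kind_a = f$kind[counted$ia], kind_b = f$kind[counted$ib],
    count = counted$count
  )
  # canonical ordering by id after resolving indices
  swap <- out$id_a > out$id_b
  out[swap, c("id_a", "id_b", "kind_a", "kind_b")] <-
    out[swap, c("id_b", "id_a", "kind_b", "kind_a")]
  out <- dplyr::summarise(dplyr::group_by(out, .data$id_a, .data$id_b,
                                          .data$kind_a, .data$kind_b),
                          count = sum(.data$count), .groups = "drop")
  dplyr::arrange(out, .data$id_a, .data$id_b)
}

#' Build a spatial interaction network from feature-pair counts
#'
#' An undirected weighted graph with an edge for every feature pair whose
#' contact count is strictly greater than `threshold` (so `threshold = 0`
#' is the "at least one read" network); the edge weight is the count.
#' Features left without any edge are omitted.
#'
#' @param counts Feature-pair count tibble (see
#'   [map_contacts_to_features()]).
#' @param threshold Minimum excluded count (default 0; strict `>`).
#' @return An `interaction_network`: a list with tibbles `edges`
#'   (`id_a`, `id_b`, `weight`, `kind_a`, `kind_b`) and `nodes`
#'   (`id`, `kind`), plus the threshold used.
#' @export
build_network <- function(counts, threshold = 0) {
  stopifnot(threshold >= 0)
  e <- as_tibble(counts)[counts$count > threshold, ]
  edges <- tibble(id_a = e$id_a, id_b = e$id_b, weight = e$count,
                  kind_a = e$kind_a, kind_b = e$kind_b)
  nodes <- dplyr::distinct(dplyr::bind_rows(
    tibble(id = edges$id_a, kind = edges$kind_a),
    tibble(id = edges$id_b, kind = edges$kind_b)
  ))
  nodes <- dplyr::arrange(nodes, .data$id)
  structure(list(edges = edges, nodes = nodes, threshold = threshold),
            class = "interaction_network")
}

#' @export
print.interaction_network <- function(x, ...) {
  cat(sprintf("<interaction_network> %d nodes, %d edges (threshold %g)\n",
              nrow(x$nodes), nrow(x$edges), x$threshold))
  kinds <- table(x$nodes$kind)
  cat("node kinds:", paste0(names(kinds), "=", kinds, collapse = ", "), "\n")
  invisible(x)
}

#' @method tidy interaction_network
#' @export
tidy.interaction_network <- function(x, ...) x$edges

#' One-row network summary
#'
#' @param x An `interaction_network`.
#' @param ... Unused.
#' @return Tibble with node/edge counts, mean degree, mean clustering
#'   coefficient and number of connected components.
#' @method glance interaction_network
#' @export
glance.interaction_network <- function(x, ...) {
  deg <- node_degrees(x)
  cc <- clustering_coefficient(x)
  comp <- if (nrow(x$nodes)) {
    g <- as_igraph(x)
    igraph::count_components(g)
  } else 0L
  tibble(
    n_nodes = nrow(x$nodes), n_edges = nrow(x$edges),
    mean_degree = if (nrow(x$nodes)) mean(deg) else NA_real_,
    mean_clustering = if (nrow(cc)) mean(cc$clustering) else NA_real_,
    n_components = comp, threshold = x$threshold
  )
}

as_igraph <- function(net) {
  igraph::graph_from_data_frame(
    net$edges[c("id_a", "id_b", "weight")],
    directed = FALSE, vertices = net$nodes
  )
}

#' Plot an interaction network
#'
#' Force-directed layout with nodes colored by feature kind and edge width
#' by contact weight.
#'
#' @param object An `interaction_network`.
#' @param seed Layout seed (default 1).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot interaction_network
#' @export
autoplot.interaction_network <- function(object, seed = 1, ...) {
  g <- as_igraph(object)
  xy <- with_seed(seed, igraph::layout_with_fr(g))
  nd <- dplyr::mutate(object$nodes, x = xy[, 1], y = xy[, 2])
  ed <- dplyr::left_join(object$edges,
                         setNames(nd[c("id", "x", "y")], c("id_a", "xa", "ya")),
                         by = "id_a")
  ed <- dplyr::left_join(ed,
                         setNames(nd[c("id", "x", "y")], c("id_b", "xb", "yb")),
                         by = "id_b")
  ggplot2::ggplot() +
    ggplot2::geom_segment(
      data = ed,
      ggplot2::aes(x = .data$xa, y = .data$ya, xend = .data$xb,
                   yend = .data$yb, linewidth = .data$weight),
      color = "grey70", alpha = 0.6
    ) +
    ggplot2::geom_point(
      data = nd, ggplot2::aes(.data$x, .data$y, color = .data$kind), size = 2
    ) +
    ggplot2::scale_linewidth(range = c(0.2, 1.5)) +
    ggplot2::theme_void()
}

#' Pick per-sample thresholds that equalize network sizes
#'
#' Sequencing depth differs between samples, so a common count threshold
#' yields networks of very different sizes. For each sample this picks the
#' smallest integer threshold `t` whose strict network (`count > t`) has at
#' most `target_edges` edges, then adds edges with `count == t` back — in
#' deterministic order (weight descending, then lexicographic pair id) —
#' until every sample's network has exactly `target_edges` edges.
#'
#' @param counts_list Named list of feature-pair count tibbles, one per
#'   sample.
#' @param target_edges Desired edge count, at most the smallest sample's
#'   total pair count.
#' @return Tibble with columns `sample`, `threshold`, `n_edges` and a
#'   list-column `network` of `interaction_network` objects.
#' @export
equalize_edges <- function(counts_list, target_edges) {
  stopifnot(length(counts_list) > 0, target_edges >= 0)
  if (is.null(names(counts_list))) {
    names(counts_list) <- paste0("sample", seq_along(counts_list))
  }
  res <- purrr::imap(counts_list, function(counts, sample) {
    counts <- as_tibble(counts)
    if (target_edges > nrow(counts)) {
      abort(sprintf("sample %s has only %d pairs; target %d unreachable.",
                    sample, nrow(counts), target_edges))
    }
    t <- 0L
    while (sum(counts$count > t) > target_edges) t <- t + 1L
    keep <- counts$count > t
    deficit <- target_edges - sum(keep)
    if (deficit > 0) {
      ties <- which(counts$count == t)
      ord <- ties[order(-counts$count[ties], counts$id_a[ties],
                        counts$id_b[ties])]
      keep[ord[seq_len(deficit)]] <- TRUE
    }
    trimmed <- counts[keep, ]
    net <- build_network(trimmed, threshold = 0)
    net$threshold <- t
    tibble(sample = sample, threshold = t, n_edges = nrow(net$edges),
           network = list(net))
  })
  dplyr::bind_rows(res)
}

# ---- graph statistics ------------------------------------------------------

# adjacency list over node indices 1..n
adjacency_list <- function(net) {
  n <- nrow(net$nodes)
  adj <- vector("list", n)
  for (i in seq_len(n)) adj[[i]] <- integer()
  if (nrow(net$edges)) {
    ia <- match(net$edges$id_a, net$nodes$id)
    ib <- match(net$edges$id_b, net$nodes$id)
    for (k in seq_along(ia)) {
      adj[[ia[k]]] <- c(adj[[ia[k]]], ib[k])
      adj[[ib[k]]] <- c(adj[[ib[k]]], ia[k])
    }
  }
  lapply(adj, unique)
}

# all-pairs BFS distances and shortest-path counts
bfs_all <- function(adj) {
  n <- length(adj)
  D <- matrix(Inf, n, n)
  S <- matrix(0, n, n)
  for (s in seq_len(n)) {
    dist <- rep(Inf, n); sigma <- numeric(n)
    dist[s] <- 0; sigma[s] <- 1
    frontier <- s
    while (length(frontier)) {
      nxt <- integer()
      for (u in frontier) {
        for (w in adj[[u]]) {
          if (is.infinite(dist[w])) {
            dist[w] <- dist[u] + 1
            nxt <- c(nxt, w)
            sigma[w] <- sigma[w] + sigma[u]
          } else if (dist[w] == dist[u] + 1) {
            sigma[w] <- sigma[w] + sigma[u]
          }
        }
      }
      frontier <- unique(nxt)
    }
    D[s, ] <- dist
    S[s, ] <- sigma
  }
  list(D = D, S = S)
}

node_degrees <- function(net) {
  n <- nrow(net$nodes)
  deg <- integer(n)
  if (nrow(net$edges)) {
    tab <- table(factor(c(match(net$edges$id_a, net$nodes$id),
                          match(net$edges$id_b, net$nodes$id)),
                        levels = seq_len(n)))
    deg <- as.integer(tab)
  }
  setNames(deg, net$nodes$id)
}

#' Node-degree distribution
#'
#' @param net An `interaction_network`.
#' @return Tibble `degree`, `n_nodes`; counts sum to the number of nodes.
#' @export
degree_histogram <- function(net) {
  deg <- node_degrees(net)
  tab <- table(deg)
  tibble(degree = as.integer(names(tab)), n_nodes = as.integer(tab))
}

#' Shortest-path-length distribution
#'
#' Histogram of unweighted shortest-path lengths over all unordered
#' reachable node pairs (edge weights are ignored for distances);
#' unreachable pairs are absent.
#'
#' @param net An `interaction_network`.
#' @return Tibble `length`, `n_pairs`.
#' @export
shortest_path_histogram <- function(net) {
  b <- bfs_all(adjacency_list(net))
  d <- b$D[upper.tri(b$D)]
  d <- d[is.finite(d) & d > 0]
  tab <- table(d)
  tibble(length = as.integer(names(tab)), n_pairs = as.integer(tab))
}

#' Clustering coefficient per node
#'
#' `C_n = 2 e_n / (k_n (k_n - 1))`, where `e_n` is the number of edges
#' among the immediate neighbors of `n` and `k_n` the number of neighbors;
#' nodes with fewer than two neighbors get 0.
#'
#' @param net An `interaction_network`.
#' @return Tibble `id`, `degree`, `clustering`.
#' @export
clustering_coefficient <- function(net) {
  adj <- adjacency_list(net)
  deg <- lengths(adj)
  cc <- vapply(seq_along(adj), function(i) {
    k <- deg[i]
    if (k < 2) return(0)
    nb <- adj[[i]]
    e <- sum(vapply(nb, function(u) sum(adj[[u]] %in% nb), 0)) / 2
    2 * e / (k * (k - 1))
  }, 0)
  tibble(id = net$nodes$id, degree = as.integer(deg), clustering = cc)
}

#' Closeness centrality per node
#'
#' The reciprocal of the mean shortest-path length from a node to every
#' node it can reach — in `[0, 1]`, high when information spreads fast
#' from the node. Isolated nodes get 0.
#'
#' @param net An `interaction_network`.
#' @return Tibble `id`, `closeness`.
#' @export
closeness_centrality <- function(net) {
  b <- bfs_all(adjacency_list(net))
  cl <- vapply(seq_len(nrow(b$D)), function(i) {
    d <- b$D[i, ]
    d <- d[is.finite(d) & d > 0]
    if (length(d) == 0) 0 else 1 / mean(d)
  }, 0)
  tibble(id = net$nodes$id, closeness = cl)
}

#' Node stress and its power-of-ten histogram
#'
#' The stress of a node is the number of shortest paths between other node
#' pairs that pass through it, counting every distinct shortest path of a
#' pair. The histogram groups nodes into bins whose widths are factors of
#' ten: `0`, `1–9`, `10–99`, and so on.
#'
#' @param net An `interaction_network`.
#' @return List with `stress` (tibble `id`, `stress`) and `histogram`
#'   (tibble `bin`, `lower`, `upper`, `n_nodes`).
#' @export
stress_distribution <- function(net) {
  adj <- adjacency_list(net)
  b <- bfs_all(adj)
  n <- length(adj)
  stress <- vapply(seq_len(n), function(v) {
    if (n < 3) return(0)
    through <- outer(b$S[, v], b$S[v, ]) *
      (outer(b$D[, v], b$D[v, ], "+") == b$D)
    through[!is.finite(through)] <- 0
    through[v, ] <- 0; through[, v] <- 0
    diag(through) <- 0
    sum(through) / 2  # ordered pairs counted twice
  }, 0)
  lower <- c(0, 10^(0:15))
  upper <- c(0, 10^(1:16) - 1)
  bin_of <- findInterval(stress, lower)
  tab <- table(factor(bin_of, levels = seq_along(lower)))
  hist <- tibble(
    bin = c("0", sprintf("%g-%g", lower[-1], upper[-1])),
    lower = lower, upper = upper, n_nodes = as.integer(tab)
  )
  hist <- hist[hist$n_nodes > 0 | hist$lower <= max(stress), ]
  list(stress = tibble(id = net$nodes$id, stress = stress),
       histogram = hist)
}

#' Topological coefficient per node
#'
#' For node `n` with neighbors `k_n >= 2`, the mean over all partners `m`
#' (nodes sharing at least one neighbor with `n`, or directly linked to it)
#' of `J(n, m)` — the number of shared neighbors, plus 1 when `n` and `m`
#' are directly linked — divided by `k_n`. Nodes with zero or one neighbor
#' get 0. Low values for high-degree nodes indicate hubs that do not share
#' their neighborhoods.
#'
#' @param net An `interaction_network`.
#' @return Tibble `id`, `topological_coefficient`.
#' @export
topological_coefficient <- function(net) {
  adj <- adjacency_list(net)
  n <- length(adj)
  tc <- vapply(seq_len(n), function(i) {
    k <- length(adj[[i]])
    if (k <= 1) return(0)
    j_vals <- vapply(setdiff(seq_len(n), i), function(m) {
      shared <- length(intersect(adj[[i]], adj[[m]]))
      direct <- m %in% adj[[i]]
      if (shared == 0 && !direct) return(NA_real_)
      shared + as.numeric(direct)
    }, 0)
    j_vals <- j_vals[!is.na(j_vals)]
    if (length(j_vals) == 0) return(0)
    mean(j_vals) / k
  }, 0)
  tibble(id = net$nodes$id, topological_coefficient = tc)
}

#' All node metrics in one table
#'
#' @param net An `interaction_network`.
#' @return Tibble `id`, `kind`, `degree`, `clustering`, `closeness`,
#'   `stress`, `topological_coefficient`.
#' @export
network_node_metrics <- function(net) {
  out <- dplyr::left_join(net$nodes, clustering_coefficient(net), by = "id")
  out <- dplyr::left_join(out, closeness_centrality(net), by = "id")
  out <- dplyr::left_join(out, stress_distribution(net)$stress, by = "id")
  dplyr::left_join(out, topological_coefficient(net), by = "id")
}

#' Fit a power law to a degree distribution
#'
#' Least-squares line through `(log10 degree, log10 count)` over degrees
#' with positive counts. A near-linear fit (high R-squared) with negative
#' slope is the scale-free signature of hub-dominated networks.
#'
#' @param degree_hist Tibble `degree`, `n_nodes` (see
#'   [degree_histogram()]); at least 3 distinct positive-count degrees.
#' @return A `scale_free_fit` object with elements `slope`, `r_squared`,
#'   `data` and the underlying `lm` fit. Supports [tidy()], [glance()] and
#'   [autoplot()].
#' @export
scale_free_fit <- function(degree_hist) {
  d <- as_tibble(degree_hist)
  d <- d[d$n_nodes > 0 & d$degree > 0, ]
  if (nrow(d) < 3) abort("need at least 3 distinct degrees with positive counts.")
  d$log_degree <- log10(d$degree)
  d$log_count <- log10(d$n_nodes)
  # exact power laws fit perfectly; lm's perfect-fit warning is expected
  fit <- suppressWarnings(lm(log_count ~ log_degree, data = d))
  structure(
    list(slope = unname(stats::coef(fit)[["log_degree"]]),
         r_squared = suppressWarnings(summary(fit)$r.squared),
         data = d, fit = fit),
    class = "scale_free_fit"
  )
}

#' @export
print.scale_free_fit <- function(x, ...) {
  cat(sprintf("<scale_free_fit> slope %.3f, R^2 %.3f over %d degrees\n",
              x$slope, x$r_squared, nrow(x$data)))
  invisible(x)
}

#' @method tidy scale_free_fit
#' @export
tidy.scale_free_fit <- function(x, ...) {
  co <- suppressWarnings(summary(x$fit)$coefficients)
  tibble(
    term = rownames(co), estimate = co[, 1], std_error = co[, 2],
    statistic = co[, 3], p_value = co[, 4]
  )
}

#' @method glance scale_free_fit
#' @export
glance.scale_free_fit <- function(x, ...) {
  tibble(slope = x$slope, r_squared = x$r_squared, n_degrees = nrow(x$data))
}

#' @method autoplot scale_free_fit
#' @export
autoplot.scale_free_fit <- function(object, ...) {
  ggplot2::ggplot(object$data,
                  ggplot2::aes(.data$log_degree, .data$log_count)) +
    ggplot2::geom_point() +
    ggplot2::geom_abline(
      slope = object$slope,
      intercept = unname(stats::coef(object$fit)[[1]]),
      linetype = 2, color = "steelblue"
    ) +
    ggplot2::labs(x = "log10 degree", y = "log10 node count",
                  title = sprintf("slope %.2f, R² %.2f",
                                  object$slope, object$r_squared))
}

#' Write a network as edge-list and node-metrics TSVs
#'
#' @param net An `interaction_network`.
#' @param edges_path Path for the weighted edge list
#'   (`id_a`, `id_b`, `weight`, `kind_a`, `kind_b`).
#' @param nodes_path Optional path for the node-metrics table (see
#'   [network_node_metrics()]).
#' @return `edges_path`, invisibly.
#' @export
write_network <- function(net, edges_path, nodes_path = NULL) {
  readr::write_tsv(net$edges, edges_path, progress = FALSE)
  if (!is.null(nodes_path)) {
    readr::write_tsv(network_node_metrics(net), nodes_path, progress = FALSE)
  }
  invisible(edges_path)
}
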