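test_that("contact ends map to containing features and cross pairs count", {
  features <- tibble::tibble(
    id = c("G1", "G2", "G3"), chrom = "chr1",
    start = c(100L, 4900L, 4950L), end = c(200L, 5100L, 5050L),
    kind = "GENE"
  )
  contacts <- tibble::tibble(chrom_a = "chr1", pos_a = 150L,
                             chrom_b = "chr1", pos_b = 5000L)
  counts <- map_contacts_to_features(contacts, features)
  # end B overlaps G2 and G3 -> both pairs incremented
  expect_equal(nrow(counts), 2)
  expect_equal(counts$count, c(1L, 1L))
  expect_setequal(counts$id_b, c("G2", "G3"))

  outside <- tibble::tibble(chrom_a = "chr1", pos_a = 150L,
                            chrom_b = "chr1", pos_b = 9000L)
  expect_equal(nrow(map_contacts_to_features(outside, features)), 0)
})

test_that("only requested feature kinds become nodes", {
  features <- tibble::tibble(
    id = c("G1", "P1"), chrom = "chr1",
    start = c(100L, 4900L), end = c(200L, 5100L),
    kind = c("GENE", "PSEUDO")
  )
  contacts <- tibble::tibble(chrom_a = "chr1", pos_a = 150L,
                             chrom_b = "chr1", pos_b = 5000L)
  expect_equal(nrow(map_contacts_to_features(contacts, features, "GENE")), 0)
  both <- map_contacts_to_features(contacts, features, c("GENE", "PSEUDO"))
  expect_equal(both$count, 1L)
})

test_that("network edges are strictly above threshold and isolated nodes absent", {
  counts <- tibble::tibble(
    id_a = c("G1", "G1"), id_b = c("G2", "G3"),
    kind_a = "GENE", kind_b = "GENE", count = c(3L, 1L)
  )
  net1 <- build_network(counts, 1)
  expect_equal(nrow(net1$edges), 1)
  expect_false("G3" %in% net1$nodes$id)
  net0 <- build_network(counts, 0)
  expect_equal(nrow(net0$edges), 2)
  # edge count is monotone non-increasing in the threshold
  sizes <- vapply(0:3, function(t) nrow(build_network(counts, t)$edges), 0L)
  expect_true(all(diff(sizes) <= 0))
})

test_that("edge equalization reproduces the worked threshold examples", {
  mk <- function(w) tibble::tibble(
    id_a = sprintf("A%02d", seq_along(w)), id_b = sprintf("B%02d", seq_along(w)),
    kind_a = "GENE", kind_b = "GENE", count = w
  )
  r1 <- equalize_edges(list(s1 = mk(c(5, 4, 3, 2, 2, 1))), 3)
  expect_equal(r1$threshold, 2L)
  expect_equal(sort(r1$network[[1]]$edges$weight, decreasing = TRUE),
               c(5, 4, 3))
  r2 <- equalize_edges(list(s2 = mk(c(9, 1, 1, 1, 1))), 3)
  expect_equal(r2$threshold, 1L)
  expect_equal(r2$n_edges, 3L)
  added <- r2$network[[1]]$edges
  expect_equal(sort(added$id_a), c("A01", "A02", "A03"))  # lexicographic ties
  r3 <- equalize_edges(list(s3 = mk(c(3, 2, 1))), 3)
  expect_equal(r3$threshold, 0L)
  expect_equal(r3$n_edges, 3L)
  expect_error(equalize_edges(list(s = mk(c(1, 2))), 5), "unreachable")
})

test_that("degree and shortest-path histograms match simple hand graphs", {
  triangle <- edges_to_network(cbind(c("a", "b", "c"), c("b", "c", "a")))
  expect_equal(degree_histogram(triangle),
               tibble::tibble(degree = 2L, n_nodes = 3L))
  expect_equal(shortest_path_histogram(triangle),
               tibble::tibble(length = 1L, n_pairs = 3L))
  star <- edges_to_network(cbind("hub", c("l1", "l2", "l3")))
  expect_equal(degree_histogram(star),
               tibble::tibble(degree = c(1L, 3L), n_nodes = c(3L, 1L)))
  path <- edges_to_network(cbind(c("a", "b"), c("b", "c")))
  expect_equal(shortest_path_histogram(path),
               tibble::tibble(length = c(1L, 2L), n_pairs = c(2L, 1L)))
  # two components: unreachable pairs absent
  two <- edges_to_network(cbind(c("a", "x"), c("b", "y")))
  expect_equal(sum(shortest_path_histogram(two)$n_pairs), 2)
})

test_that("per-node statistics match their definitions on hand graphs", {
  triangle <- edges_to_network(cbind(c("a", "b", "c"), c("b", "c", "a")))
  expect_equal(clustering_coefficient(triangle)$clustering, rep(1, 3))
  expect_equal(closeness_centrality(triangle)$closeness, rep(1, 3))
  expect_equal(stress_distribution(triangle)$stress$stress, rep(0, 3))
  expect_equal(topological_coefficient(triangle)$topological_coefficient,
               rep(1, 3))

  path <- edges_to_network(cbind(c("a", "b"), c("b", "c")))
  pm <- network_node_metrics(path)
  expect_equal(pm$clustering[pm$id == "b"], 0)
  expect_equal(pm$stress[pm$id == "b"], 1)
  expect_equal(pm$closeness[pm$id == "a"], 1 / mean(c(1, 2)))

  star <- edges_to_network(cbind("hub", c("l1", "l2", "l3")))
  sm <- network_node_metrics(star)
  expect_equal(sm$stress[sm$id == "hub"], 3)
  expect_equal(sm$topological_coefficient[sm$id == "l1"], 0)  # degree 1

  ring4 <- edges_to_network(cbind(c("a", "b", "c", "d"),
                                  c("b", "c", "d", "a")))
  tc <- topological_coefficient(ring4)
  expect_equal(tc$topological_coefficient, rep(2 / 3, 4))

  # degree 3 with exactly one edge among neighbors -> clustering 1/3
  g <- edges_to_network(cbind(c("x", "x", "x", "n1"),
                              c("n1", "n2", "n3", "n2")))
  expect_equal(clustering_coefficient(g)$clustering[
    clustering_coefficient(g)$id == "x"], 1 / 3)
})

test_that("all six statistics agree with independent oracles on random graphs", {
  for (s in 1:20) {
    net <- random_network(n = 5 + (s %% 21), p = 0.2, seed = s)
    expect_network_matches_oracles(net)
  }
})

test_that("exact power laws fit with the expected slope and R squared", {
  hist <- tibble::tibble(degree = c(1L, 2L, 4L, 8L),
                         n_nodes = c(64L, 16L, 4L, 1L))
  fit <- scale_free_fit(hist)
  expect_equal(fit$slope, -2, tolerance = 1e-12)
  expect_equal(fit$r_squared, 1, tolerance = 1e-12)
  flat <- scale_free_fit(tibble::tibble(degree = c(1L, 2L, 4L),
                                        n_nodes = c(5L, 5L, 5L)))
  expect_equal(flat$slope, 0, tolerance = 1e-12)
  expect_error(scale_free_fit(tibble::tibble(degree = 1:2, n_nodes = c(3L, 1L))),
               "at least 3")
})

test_that("preferential-attachment networks look scale free", {
  for (s in 1:10) {
    g <- withr::with_seed(s, igraph::sample_pa(500, directed = FALSE))
    el <- igraph::as_edgelist(g)
    net <- edges_to_network(cbind(paste0("v", el[, 1]), paste0("v", el[, 2])))
    fit <- scale_free_fit(degree_histogram(net))
    expect_lt(fit$slope, -1)
    expect_gt(fit$r_squared, 0.7)
  }
})

test_that("mixed-kind networks keep gene and TFBS nodes with all edge types", {
  features <- tibble::tibble(
    id = c("G1", "G2", "T1", "T2"), chrom = "chr1",
    start = c(100L, 10000L, 20000L, 30000L),
    end = c(500L, 10500L, 20200L, 30200L),
    kind = c("GENE", "GENE", "TFBS", "TFBS")
  )
  contacts <- tibble::tibble(
    chrom_a = "chr1", pos_a = c(200L, 200L, 20100L),
    chrom_b = "chr1", pos_b = c(10200L, 20100L, 30100L)
  )
  counts <- map_contacts_to_features(contacts, features, c("GENE", "TFBS"))
  net <- build_network(counts, 0)
  pair_kinds <- paste(net$edges$kind_a, net$edges$kind_b)
  expect_setequal(pair_kinds, c("GENE GENE", "GENE TFBS", "TFBS TFBS"))
  expect_setequal(unique(net$nodes$kind), c("GENE", "TFBS"))
})
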