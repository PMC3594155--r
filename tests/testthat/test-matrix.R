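genome <- two_chrom_genome()

test_that("positions land in floor((p-1)/resolution) bins", {
  contacts <- tibble::tibble(chrom_a = "chr1", pos_a = 1500000L,
                             chrom_b = "chr1", pos_b = 3200000L)
  m <- bin_contacts(contacts, genome, 1e6, "chr1")
  expect_equal(m$values[2, 4], 1)
  expect_equal(m$values[4, 2], 1)
  expect_equal(sum(m$values), 2)
})

test_that("repeated contacts accumulate and intra matrices stay symmetric", {
  contacts <- tibble::tibble(
    chrom_a = "chr1", pos_a = rep(500L, 3),
    chrom_b = "chr1", pos_b = rep(2000500L, 3)
  )
  m <- bin_contacts(contacts, genome, 1e6, "chr1")
  expect_equal(m$values[1, 3], 3)
  expect_identical(m$values, t(m$values))
})

test_that("inter matrices have one cell per contact and correct dimensions", {
  contacts <- tibble::tibble(chrom_a = "chr1", pos_a = 500L,
                             chrom_b = "chr2", pos_b = 500L)
  m <- bin_contacts(contacts, genome, 1e6, "chr1", "chr2")
  expect_equal(dim(m$values), c(5, 5))
  expect_equal(m$values[1, 1], 1)
  expect_equal(sum(m$values), 1)
})

test_that("same-bin contacts are counted once on the diagonal", {
  contacts <- tibble::tibble(chrom_a = "chr1", pos_a = 100000L,
                             chrom_b = "chr1", pos_b = 200000L)
  m <- bin_contacts(contacts, genome, 1e6, "chr1")
  expect_equal(m$values[1, 1], 1)
  expect_equal(sum(m$values[upper.tri(m$values, diag = TRUE)]), 1)
})

test_that("binned counts conserve the filtered contact total", {
  p <- sim_params(n_pairs = 2000, seed = 21)
  sim <- simulate_genome(p)
  contacts <- filter_pairs(simulate_pairs(sim$genome, p), sim$genome)
  total <- 0
  for (ch in sim$genome$chrom) {
    v <- bin_contacts(contacts, sim$genome, 1e6, ch)$values
    total <- total + sum(v[upper.tri(v, diag = TRUE)])
  }
  total <- total + sum(bin_contacts(contacts, sim$genome, 1e6,
                                    "chrA", "chrB")$values)
  expect_equal(total, nrow(contacts))
})

test_that("fine bins aggregate exactly to coarse bins", {
  p <- sim_params(n_pairs = 3000, seed = 22)
  sim <- simulate_genome(p)
  contacts <- filter_pairs(simulate_pairs(sim$genome, p), sim$genome)
  fine <- bin_contacts(contacts, sim$genome, 1e4, "chrA")$values
  coarse <- bin_contacts(contacts, sim$genome, 1e6, "chrA")$values
  agg <- matrix(0, nrow(coarse), ncol(coarse))
  groups <- (seq_len(nrow(fine)) - 1) %/% 100 + 1
  for (i in seq_len(nrow(coarse))) {
    for (j in seq_len(ncol(coarse))) {
      block <- fine[groups == i, groups == j, drop = FALSE]
      agg[i, j] <- if (i == j) {
        # symmetric storage counts distinct-bin contacts twice within a
        # diagonal block, same-bin contacts once on its diagonal
        (sum(block) + sum(diag(block))) / 2
      } else {
        sum(block)
      }
    }
  }
  expect_equal(agg, unname(coarse))
})

test_that("positions beyond the chromosome end are an input error", {
  contacts <- tibble::tibble(chrom_a = "chr1", pos_a = 6000000L,
                             chrom_b = "chr1", pos_b = 100L)
  expect_error(bin_contacts(contacts, genome, 1e6, "chr1"), "beyond")
})

test_that("visualization cap clamps values without touching small ones", {
  m <- contact_matrix(matrix(c(120, 7, 7, 120), 2, 2))
  capped <- cap_for_visualization(m, 50)
  expect_equal(as.vector(capped$values), c(50, 7, 7, 50))
  binary <- cap_for_visualization(m, 1)
  expect_true(all(binary$values %in% c(0, 1)))
})

test_that("region profiles add intra and inter row totals", {
  intra <- contact_matrix(matrix(c(0, 2, 2, 0), 2, 2), "chr1",
                          resolution = 100)
  inter <- contact_matrix(matrix(c(1, 0, 0, 0), 2, 2), "chr1", "chr2",
                          resolution = 100)
  prof <- region_contact_profile(list(intra, inter), "chr1")
  expect_equal(prof$contacts, c(3, 2))
  prof2 <- region_contact_profile(list(intra), "chr1")
  expect_equal(prof2$contacts, c(2, 2))
})

test_that("matrix TSV and triplet output round-trip values and labels", {
  p <- sim_params(n_pairs = 500, seed = 23)
  sim <- simulate_genome(p)
  contacts <- filter_pairs(simulate_pairs(sim$genome, p), sim$genome)
  m <- bin_contacts(contacts, sim$genome, 1e6, "chrA")
  f <- withr::local_tempfile(fileext = ".tsv")
  write_matrix_tsv(m, f)
  back <- read_matrix_tsv(f)
  expect_equal(back$values, m$values)
  expect_equal(back$row_bins$start, m$row_bins$start)

  ft <- withr::local_tempfile(fileext = ".tsv")
  write_matrix_triplets(m, ft)
  trip <- readr::read_tsv(ft, show_col_types = FALSE)
  expect_equal(sum(trip$value),
               sum(m$values[upper.tri(m$values, diag = TRUE)]))
})

test_that("tidy and glance expose the matrix as tables", {
  m <- contact_matrix(matrix(1:4, 2, 2) * 1.0, "chr1", "chr2",
                      resolution = 10)
  td <- tidy(m)
  expect_equal(nrow(td), 4)
  expect_equal(td$value, c(1, 2, 3, 4))
  g <- glance(m)
  expect_equal(g$total, 10)
  expect_equal(g$n_row, 2)
})
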