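genome <- two_chrom_genome()

test_that("unique-unique pairs are accepted and canonically ordered", {
  pairs <- make_pairs(list(
    unique_pair("r1", "chr1", 100000, "chr1", 105000),
    unique_pair("r2", "chr1", 300000, "chr1", 200000),   # needs swap
    unique_pair("r3", "chr2", 50000, "chr1", 400000)     # chrom swap
  ))
  cls <- classify_pairs(pairs, genome)
  expect_equal(cls$status, rep("accepted", 3))
  expect_equal(cls$pos_a, c(100000L, 200000L, 400000L))
  expect_equal(cls$chrom_a, c("chr1", "chr1", "chr1"))
  expect_equal(cls$chrom_b[3], "chr2")
})

test_that("ends with three or more candidates are discarded under both strategies", {
  pairs <- make_pairs(list(
    list(id = "r1",
         end1 = list(c("chr1", 1000), c("chr1", 9000), c("chr2", 500)),
         end2 = list(c("chr1", 50000)))
  ))
  for (strategy in c("strict_unique", "four_case")) {
    cls <- classify_pairs(pairs, genome, strategy)
    expect_equal(cls$status, "multi_mapped")
  }
})

test_that("strict strategy rejects any multi-candidate end that four_case resolves", {
  pairs <- make_pairs(list(
    list(id = "r1", end1 = list(c("chr2", 50000)),
         end2 = list(c("chr2", 51000), c("chr1", 900000)))
  ))
  strict <- classify_pairs(pairs, genome, "strict_unique")
  expect_equal(strict$status, "multi_mapped")
  # four_case: chr2:51000 is within insert_length of the unique end, so the
  # other candidate chr1:900000 becomes the contact partner
  fc <- classify_pairs(pairs, genome, "four_case")
  expect_equal(fc$status, "accepted")
  expect_equal(fc$chrom_a, "chr1")
  expect_equal(fc$pos_a, 900000L)
  expect_equal(fc$chrom_b, "chr2")
  expect_equal(fc$pos_b, 50000L)
})

test_that("case 2/3 pairs with no candidate near the unique end are invalid", {
  pairs <- make_pairs(list(
    list(id = "far", end1 = list(c("chr1", 100000)),
         end2 = list(c("chr1", 500000), c("chr2", 900000))),
    list(id = "mirror", end1 = list(c("chr1", 500000), c("chr2", 900000)),
         end2 = list(c("chr1", 100000)))
  ))
  cls <- classify_pairs(pairs, genome, "four_case")
  expect_equal(cls$status, c("invalid_case", "invalid_case"))
})

test_that("case 4 validity requires both candidate distances below read length", {
  pairs <- make_pairs(list(
    list(id = "ok",
         end1 = list(c("chr1", 100000), c("chr2", 700000)),
         end2 = list(c("chr1", 100050), c("chr2", 700080))),
    list(id = "bad",
         end1 = list(c("chr1", 100000), c("chr2", 700000)),
         end2 = list(c("chr1", 100050), c("chr2", 705000)))
  ))
  cls <- classify_pairs(pairs, genome, "four_case")
  expect_equal(cls$status[cls$read_id == "ok"], "accepted")
  # case 4 emits the pair of first candidates (A, C)
  expect_equal(cls$pos_a[cls$read_id == "ok"], 100000L)
  expect_equal(cls$pos_b[cls$read_id == "ok"], 100050L)
  expect_equal(cls$status[cls$read_id == "bad"], "invalid_case")
})

test_that("separation filter keeps inter pairs and enforces the 2 Kb boundary", {
  contacts <- tibble::tibble(
    chrom_a = c("chr1", "chr1", "chr1"),
    pos_a = c(1000L, 1000L, 1000L),
    chrom_b = c("chr1", "chr1", "chr2"),
    pos_b = c(2999L, 3000L, 1000L)
  )
  expect_equal(apply_separation_filter(contacts), c(FALSE, TRUE, TRUE))
})

test_that("filtering conserves records in the stats and reports planted reasons", {
  pairs <- make_pairs(list(
    unique_pair("r1", "chr1", 100000, "chr1", 200000),
    unique_pair("r2", "chr1", 300000, "chr2", 100000),
    unique_pair("r3", "chr2", 10000, "chr2", 500000),
    list(id = "r4", end1 = list(c("chr1", 1), c("chr1", 2), c("chr1", 3)),
         end2 = list(c("chr1", 50000))),
    unique_pair("r5", "chr1", 10000, "chr1", 11000)  # sep 1000 < 2000
  ))
  contacts <- filter_pairs(pairs, genome)
  stats <- filter_stats(contacts)
  expect_equal(nrow(contacts), 3)
  expect_equal(sum(stats$n), 5)
  expect_equal(stats$n[stats$reason == "accepted"], 3L)
  expect_equal(stats$n[stats$reason == "multi_mapped"], 1L)
  expect_equal(stats$n[stats$reason == "short_separation"], 1L)
})

test_that("empty input gives zero contacts and all-zero stats", {
  contacts <- filter_pairs(make_pairs(list()), genome)
  expect_equal(nrow(contacts), 0)
  expect_true(all(filter_stats(contacts)$n == 0))
})

test_that("duplicate identical pairs are kept unless dedup is requested", {
  recs <- replicate(4, unique_pair("x", "chr1", 100000, "chr1", 200000),
                    simplify = FALSE)
  for (i in seq_along(recs)) recs[[i]]$id <- paste0("r", i)
  pairs <- make_pairs(recs)
  expect_equal(nrow(filter_pairs(pairs, genome)), 4)
  expect_equal(nrow(filter_pairs(pairs, genome, dedup = TRUE)), 1)
})

test_that("output contact multiset is invariant to record order", {
  p <- sim_params(n_pairs = 300, seed = 42)
  sim <- simulate_genome(p)
  pairs <- simulate_pairs(sim$genome, p)
  ids <- unique(pairs$read_id)
  perm <- withr::with_seed(7, sample(ids))
  shuffled <- dplyr::arrange(pairs, match(read_id, perm), end, cand)
  c1 <- filter_pairs(pairs, sim$genome)
  c2 <- filter_pairs(shuffled, sim$genome)
  sort_key <- function(x) dplyr::arrange(tibble::as_tibble(x),
                                         chrom_a, pos_a, chrom_b, pos_b)
  expect_equal(sort_key(c1), sort_key(c2))
  expect_equal(filter_stats(c1), filter_stats(c2))
})

test_that("filtering already-filtered contacts changes nothing", {
  p <- sim_params(n_pairs = 500, seed = 5)
  sim <- simulate_genome(p)
  contacts <- filter_pairs(simulate_pairs(sim$genome, p), sim$genome)
  keep <- apply_separation_filter(contacts)
  expect_true(all(keep))
})

test_that("strict_unique acceptances are a subset of four_case acceptances", {
  p <- sim_params(n_pairs = 400, seed = 9)
  sim <- simulate_genome(p)
  pairs <- simulate_pairs(sim$genome, p)
  strict <- classify_pairs(pairs, sim$genome, "strict_unique")
  fc <- classify_pairs(pairs, sim$genome, "four_case")
  strict_acc <- strict$read_id[strict$status == "accepted"]
  fc_acc <- fc$read_id[fc$status == "accepted"]
  expect_true(all(strict_acc %in% fc_acc))
})

test_that("unknown chromosomes are an input error", {
  pairs <- make_pairs(list(unique_pair("r1", "chrX", 100, "chr1", 5000)))
  expect_error(classify_pairs(pairs, genome), "unknown chromosome")
})

test_that("pair tables round-trip through both dialects", {
  pairs <- make_pairs(list(
    unique_pair("r1", "chr1", 100000, "chr1", 200000),
    list(id = "r2", end1 = list(c("chr1", 5000), c("chr2", 700)),
         end2 = list(c("chr2", 40000)))
  ))
  full <- withr::local_tempfile(fileext = ".tsv")
  write_pairs(pairs, full)
  expect_equal(as.data.frame(read_pairs(full)), as.data.frame(pairs))

  uniq <- make_pairs(list(unique_pair("r1", "chr1", 100000, "chr2", 200000)))
  simple <- withr::local_tempfile(fileext = ".tsv")
  write_pairs(uniq, simple, dialect = "simple")
  back <- read_pairs(simple)
  expect_equal(back$chrom, uniq$chrom)
  expect_equal(back$pos, uniq$pos)
})

test_that("malformed pair-table lines are reported with their line number", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("r1\t1\tchr1\t100\t+\t1\tchr1\t5000\t+\t100",
               "r2\t2\tchr1\t100\t+"), f)
  expect_error(read_pairs(f), "line 2")
})
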