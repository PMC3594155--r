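test_that("row correlations match a direct Pearson computation", {
  v <- rbind(c(5, 1, 0, 2), c(4, 2, 1, 2), c(0, 3, 8, 1), c(1, 2, 7, 0))
  v <- v + t(v)  # symmetric counts fixture
  cm <- correlation_matrix(contact_matrix(v))
  pearson <- function(x, y) {
    mean((x - mean(x)) * (y - mean(y))) /
      sqrt(mean((x - mean(x))^2) * mean((y - mean(y))^2))
  }
  for (i in 1:4) {
    for (j in 1:4) {
      expect_equal(cm$values[i, j], pearson(v[i, ], v[j, ]),
                   tolerance = 1e-12)
    }
  }
})

test_that("identical rows correlate at 1 and reversed rows at -1", {
  v <- rbind(c(0, 1, 2), c(0, 1, 2), c(2, 1, 0))
  cm <- correlation_matrix(contact_matrix(v))
  expect_equal(cm$values[1, 2], 1)
  expect_equal(cm$values[1, 3], -1)
  expect_equal(diag(cm$values), rep(1, 3), ignore_attr = TRUE)
})

test_that("constant rows are flagged undefined and stored as zero", {
  v <- rbind(c(1, 2, 3), c(5, 5, 5), c(3, 2, 1))
  cm <- correlation_matrix(contact_matrix(v))
  expect_equal(cm$values[2, ], c(0, 0, 0), ignore_attr = TRUE)
  expect_true(1L %in% cm$undefined_bins)
  expect_error(correlation_matrix(contact_matrix(matrix(1, 1, 1))),
               "2 columns")
})

test_that("difference matrices are absolute and symmetric in their arguments", {
  c1 <- correlation_matrix(contact_matrix(random_symmetric(6, 1)))
  c2 <- correlation_matrix(contact_matrix(random_symmetric(6, 2)))
  d12 <- difference_matrix(c1, c2)
  d21 <- difference_matrix(c2, c1)
  expect_equal(d12$values, d21$values)
  expect_true(all(d12$values >= 0))
  expect_equal(max(difference_matrix(c1, c1)$values), 0)
})

test_that("correlation changes are classified by sign, value and tolerance", {
  base <- contact_matrix(random_symmetric(2, 3))
  c1 <- correlation_matrix(base)
  c2 <- c1
  c1$values <- matrix(c(0.5, 0.5, 0.5, 0.5), 2, 2)
  c2$values <- matrix(c(-0.2, 0.2, 0.5, 0.5), 2, 2)
  cls <- classify_correlation_change(c1, c2)
  expect_equal(cls$change[cls$bin_a == 0 & cls$bin_b == 0], "sign_change")
  expect_equal(cls$change[cls$bin_a == 1 & cls$bin_b == 0], "value_change")
  expect_equal(cls$change[cls$bin_a == 0 & cls$bin_b == 1], "unchanged")
})

test_that("Poisson significance matches brute-force pmf summation", {
  # independent oracle: direct partial sums of the Poisson pmf
  pmf <- function(k, lambda) exp(-lambda) * lambda^k / factorial(k)
  p_gt <- function(m, lambda) sum(pmf((m + 1):170, lambda))
  for (lambda in c(0.5, 2, 10)) {
    n <- 51
    v <- matrix(0, n, n)
    v[upper.tri(v)] <- rep_len(0:50, sum(upper.tri(v)))
    v <- v + t(v)
    m <- contact_matrix(v)
    # pin lambda by construction: check against the matrix's own estimate
    sig <- poisson_significance(m)
    lam <- sig$lambda
    for (count in c(0, 1, 2, 5, 17, 50)) {
      expect_equal(unname(sig$values[v == count][1]), p_gt(count, lam),
                   tolerance = 1e-12)
    }
  }
})

test_that("lambda is the off-diagonal mean and p(2) at lambda 2 is 1 - 5/e^2", {
  v <- matrix(2, 4, 4)
  diag(v) <- 99  # diagonal must not contaminate lambda
  sig <- poisson_significance(contact_matrix(v))
  expect_equal(sig$lambda, 2)
  expect_equal(sig$values[1, 2], 1 - 5 * exp(-2), tolerance = 1e-12)
  # Pr(X > 0) = 1 - e^-lambda
  v2 <- v; v2[1, 2] <- 0; v2[2, 1] <- 0
  sig2 <- poisson_significance(contact_matrix(v2))
  expect_equal(sig2$values[1, 2], 1 - exp(-sig2$lambda), tolerance = 1e-12)
})

test_that("significance is monotone non-increasing in the observed count", {
  v <- random_symmetric(9, 12) * 4
  m <- contact_matrix(round(v))
  sig <- poisson_significance(m)
  ord <- order(as.vector(m$values))
  expect_true(all(diff(as.vector(sig$values)[ord]) <= 1e-15))
})

test_that("observed/expected ratios reproduce the three-chromosome example", {
  counts <- tibble::tibble(chrom_a = c("1", "1", "2"),
                           chrom_b = c("2", "3", "3"),
                           count = c(10, 20, 30))
  oe <- observed_expected_ratios(counts)
  f <- attr(oe, "fractions")
  expect_equal(f$fraction, c(0.5, 2 / 3, 5 / 6))
  expect_equal(sum(f$fraction), 2)
  r12 <- oe$ratio[oe$chrom_a == "1" & oe$chrom_b == "2"]
  expect_equal(r12, 0.5)
  expect_equal(oe$expected[oe$chrom_a == "1" & oe$chrom_b == "2"], 20)
})

test_that("ratios are constant when counts match the expectation model", {
  # the row-sum fraction map is self-consistent exactly when all
  # fractions are equal, i.e. on equal-count fixtures of any size
  for (n in c(3, 4, 6)) {
    pairs <- t(utils::combn(n, 2))
    eq <- observed_expected_ratios(tibble::tibble(
      chrom_a = paste0("c", pairs[, 1]), chrom_b = paste0("c", pairs[, 2]),
      count = 7
    ))
    expect_lt(max(eq$ratio) - min(eq$ratio), 1e-12)
    expect_equal(attr(eq, "fractions")$fraction, rep(2 / n, n))
  }
})

test_that("cross-sample correlations behave like Pearson", {
  v1 <- c(1, 4, 2, 8)
  out <- cross_sample_correlation(list(a = v1, b = v1, c = -v1))
  expect_equal(out$r[out$sample_a == "a" & out$sample_b == "b"], 1)
  expect_equal(out$r[out$sample_a == "a" & out$sample_b == "c"], -1)
  expect_equal(out$r[out$sample_a == "a" & out$sample_b == "a"], 1)
  mats <- withr::with_seed(4, matrix(stats::rnorm(30), 10, 3))
  colnames(mats) <- c("x", "y", "z")
  res <- cross_sample_correlation(mats)
  expect_equal(res$r[res$sample_a == "x" & res$sample_b == "y"],
               stats::cor(mats[, 1], mats[, 2]))
})
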