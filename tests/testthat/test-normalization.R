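test_that("zero-count filter keeps genes with at most the tolerated zeros", {
  counts <- matrix(100L, 4, 18,
                   dimnames = list(paste0("g", 1:4),
                                   default_design()$sample))
  counts[2, 1:13] <- 0L  # zeros in 13 of 18 samples -> removed at 12
  counts[3, 1:12] <- 0L  # exactly 12 zeros -> retained
  cm <- tiny_counts(counts)
  kept <- filter_zero_genes(cm, 12)
  expect_equal(rownames(kept$counts), c("g1", "g3", "g4"))
  # idempotent
  expect_equal(filter_zero_genes(kept, 12)$counts, kept$counts)
  # brute-force recount on a random fixture
  rc <- random_counts(80, seed = 21, mu = 3, size = 0.5)
  kept2 <- filter_zero_genes(rc, 2)
  brute <- rownames(rc$counts)[apply(rc$counts, 1,
                                     function(x) sum(x == 0) <= 2)]
  expect_equal(rownames(kept2$counts), brute)
  allz <- tiny_counts(matrix(c(0L, 5L, 5L, 0L), 2, 2,
                             dimnames = list(NULL,
                                             c("WT_none_0", "WT_SOB_0.5"))))
  expect_warning(filter_zero_genes(allz, 0), "all genes removed")
})

test_that("FPKM matches its defining formula", {
  counts <- cbind(s1 = c(10L, 999990L))
  colnames(counts) <- "WT_none_0"
  cm <- tiny_counts(counts, lengths = c(1000, 5000))
  f <- fpkm(cm)
  # count 10, length 1000 bp, library 1e6 -> FPKM 10
  expect_equal(unname(f[1, 1]), 10)
  expect_identical(attr(f, "transform"), "fpkm")
  # zero count -> 0; random fixture equals per-cell recomputation
  rc <- random_counts(30, seed = 4)
  rc$counts[5, 2] <- 0L
  f2 <- fpkm(rc)
  expect_equal(unname(f2[5, 2]), 0)
  lib <- colSums(rc$counts)
  oracle <- rc$counts * 1e9 / outer(rc$lengths_bp, lib)
  expect_equal(unclass(f2), oracle, ignore_attr = TRUE)
  # scale equivariance: doubling one column leaves its FPKM unchanged
  rc2 <- rc
  rc2$counts[, 3] <- rc2$counts[, 3] * 2L
  expect_equal(unclass(fpkm(rc2))[, 3], unclass(f2)[, 3],
               tolerance = 1e-12)
  # zero library size is an error naming the sample
  rc$counts[, 2] <- 0L
  expect_error(fpkm(rc), "WT_SOB_0.5")
})

test_that("log2 + quantile normalization equalizes column distributions", {
  # hand case: post-log columns (1,3) and (2,6) both become (1.5, 4.5)
  vals <- cbind(a = 2^c(1, 3) - 1, b = 2^c(2, 6) - 1)
  rownames(vals) <- c("g1", "g2")
  colnames(vals) <- c("WT_none_0", "WT_SOB_0.5")
  qn <- log2_quantile(expression_matrix(vals, "fpkm"))
  expect_equal(unclass(qn),
               cbind(WT_none_0 = c(1.5, 4.5), WT_SOB_0.5 = c(1.5, 4.5)),
               ignore_attr = TRUE)
  # FPKM 0 -> log2(1) = 0 before the quantile step
  expect_equal(log2(0 + 1), 0)
  # identical columns are unchanged up to the common profile
  same <- matrix(c(4, 9, 1), 3, 3,
                 dimnames = list(paste0("g", 1:3),
                                 c("WT_none_0", "WT_SOB_0.5", "WT_SOB_12")))
  qs <- log2_quantile(expression_matrix(same, "fpkm"))
  expect_equal(qs[, 1], qs[, 2])
  expect_equal(unname(sort(qs[, 1])), unname(log2(sort(same[, 1]) + 1)))
  # sorted multisets identical across columns on a realistic fixture
  rc <- random_counts(200, seed = 6)
  q2 <- log2_quantile(fpkm(rc))
  s <- apply(q2, 2, sort)
  expect_true(all(s == s[, 1]))
  # agreement with limma on a tie-free fixture
  lg <- log2(unclass(fpkm(rc)) + 1)
  expect_true(all(!apply(lg, 2, anyDuplicated)))
  expect_equal(unclass(q2), limma::normalizeQuantiles(lg, ties = FALSE),
               tolerance = 1e-12, ignore_attr = TRUE)
  # single column: warn, quantile step is the identity
  one <- expression_matrix(vals[, 1, drop = FALSE], "fpkm")
  expect_warning(q1 <- log2_quantile(one), "single column")
  expect_equal(unclass(q1), log2(vals[, 1, drop = FALSE] + 1),
               ignore_attr = TRUE)
})

test_that("logCLR centers gene profiles exactly", {
  counts <- rbind(g1 = c(1L, 1L, 1L, 1L),
                  g2 = c(1L, 3L, 1L, 3L))
  colnames(counts) <- c("WT_none_0", "WT_SOB_0.5", "WT_SOB_12", "WT_HT_0.5")
  lc <- logclr(tiny_counts(counts))
  expect_equal(unname(lc[1, ]), rep(0, 4))
  # gene (1,3) over two samples: -ln2/2, +ln2/2
  two <- tiny_counts(matrix(c(1L, 3L), 1, 2,
                            dimnames = list("g1",
                                            c("WT_none_0", "WT_SOB_0.5"))))
  lc2 <- logclr(two)
  expect_equal(unname(lc2[1, ]), c(-log(2) / 2, log(2) / 2))
  # every row sums to zero
  rc <- random_counts(100, seed = 13)
  expect_lt(max(abs(rowSums(logclr(rc)))), 1e-9)
  # TMM-scaled variant stays centered and records the order
  lct <- logclr(rc, tmm_scale = TRUE)
  expect_lt(max(abs(rowSums(lct))), 1e-9)
  expect_true(attr(lct, "tmm_scaled"))
})

test_that("TMM factors match a step-by-step recomputation and edgeR", {
  rc <- random_counts(50, seed = 9)
  rc$counts[3, 2] <- 0L
  f <- tmm_factors(rc)
  expect_equal(exp(mean(log(f))), 1, tolerance = 1e-9)

  # independent step-by-step recomputation of the trimmed weighted mean
  counts <- rc$counts
  lib <- colSums(counts)
  f75 <- sapply(1:4, function(j) quantile(counts[, j], 0.75) / lib[j])
  ref <- which.min(abs(f75 - mean(f75)))
  oracle <- sapply(1:4, function(j) {
    m <- log2((counts[, j] / lib[j]) / (counts[, ref] / lib[ref]))
    a <- (log2(counts[, j] / lib[j]) + log2(counts[, ref] / lib[ref])) / 2
    v <- (lib[j] - counts[, j]) / (lib[j] * counts[, j]) +
      (lib[ref] - counts[, ref]) / (lib[ref] * counts[, ref])
    ok <- is.finite(m) & is.finite(a)
    m <- m[ok]; a <- a[ok]; v <- v[ok]
    n <- length(m)
    keep <- rank(m) >= floor(0.3 * n) + 1 & rank(m) <= n - floor(0.3 * n) &
      rank(a) >= floor(0.05 * n) + 1 & rank(a) <= n - floor(0.05 * n)
    2^(sum(m[keep] / v[keep]) / sum(1 / v[keep]))
  })
  oracle <- oracle / exp(mean(log(oracle)))
  expect_equal(unname(f), unname(oracle), tolerance = 1e-12)
  # and the established implementation agrees
  expect_equal(unname(f),
               unname(edgeR::calcNormFactors(counts, method = "TMM")),
               tolerance = 1e-12)

  # identical columns -> all factors 1
  same <- tiny_counts(matrix(rep(c(5L, 80L, 200L), 3), 3, 3,
                             dimnames = list(NULL,
                                             c("WT_none_0", "WT_SOB_0.5",
                                               "WT_SOB_12"))))
  expect_equal(unname(tmm_factors(same)), rep(1, 3))
  # exact proportionality: M values vanish, factors 1
  prop <- same
  prop$counts[, 2] <- prop$counts[, 1] * 2L
  expect_equal(unname(tmm_factors(prop)), rep(1, 3))
  # all-zero column refused
  z <- same
  z$counts[, 3] <- 0L
  expect_error(tmm_factors(z), "WT_SOB_12")
})

test_that("sample correlation is exact Pearson with missing for degenerate columns", {
  withr::with_seed(2, {
    m <- matrix(rnorm(40), 10, 4,
                dimnames = list(paste0("g", 1:10), paste0("s", 1:4)))
  })
  m[, 2] <- m[, 1]            # duplicate -> r = 1
  m[, 3] <- -(m[, 1] - mean(m[, 1])) + mean(m[, 1])  # centered negation -> -1
  r <- sample_correlation(expression_matrix(m, "logclr"))
  expect_equal(unname(r[1, 2]), 1)
  expect_equal(unname(r[1, 3]), -1)
  expect_equal(diag(r), setNames(rep(1, 4), colnames(m)))
  # brute-force pairwise Pearson
  for (i in 1:3) for (j in (i + 1):4)
    expect_equal(r[i, j], cor(m[, i], m[, j]), ignore_attr = TRUE)
  # zero-variance column reported as missing, not zero
  m[, 4] <- 7
  r2 <- sample_correlation(expression_matrix(m, "logclr"))
  expect_true(all(is.na(r2[4, -4])))
  expect_equal(unname(r2[4, 4]), 1)
})
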