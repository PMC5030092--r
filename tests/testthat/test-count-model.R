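toy_fragments <- function() {
  data.frame(contig = "chr", start = c(0L, 21L), end = c(21L, 100L),
             id = c("f1", "f2"), stringsAsFactors = FALSE)
}

test_that("reads are assigned to the fragment containing their 5' start", {
  frags <- toy_fragments()
  none <- count_reads_to_fragments(
    data.frame(contig = character(0), start = integer(0)), frags)
  expect_equal(unname(none), c(0L, 0L))

  reads <- data.frame(contig = "chr", start = c(5L, 21L, 22L))
  expect_equal(unname(count_reads_to_fragments(reads, frags)), c(1L, 2L))

  # half-open convention: a read starting exactly on a boundary goes right
  boundary <- data.frame(contig = "chr", start = 21L)
  expect_equal(unname(count_reads_to_fragments(boundary, frags)), c(0L, 1L))

  # minus-strand 5' end is end - 1
  minus <- data.frame(contig = "chr", start = 15L, end = 40L, strand = "-")
  expect_equal(unname(count_reads_to_fragments(minus, frags)), c(0L, 1L))

  # unknown contigs are dropped with a warning, off-contig with a message
  mixed <- data.frame(contig = c("chr", "chrX"), start = c(5L, 5L))
  expect_warning(cnt <- count_reads_to_fragments(mixed, frags), "dropped")
  expect_equal(unname(cnt), c(1L, 0L))
  off <- data.frame(contig = "chr", start = c(5L, 500L))
  expect_message(cnt <- count_reads_to_fragments(off, frags), "outside")
  expect_equal(unname(cnt), c(1L, 0L))

  # unsorted fragments are handled; counts stay in input row order
  shuffled <- frags[2:1, ]
  expect_equal(count_reads_to_fragments(reads, shuffled),
               c(f2 = 2L, f1 = 1L))
})

test_that("low-coverage filtering drops a fragment when any sample is below threshold", {
  m <- matrix(c(12, 15, 9, 30, 10, 10), ncol = 2, byrow = TRUE,
              dimnames = list(c("a", "b", "c"), NULL))
  expect_equal(rownames(filter_low_coverage(m, 10)), c("a", "c"))
  expect_equal(filter_low_coverage(m, 0), m)
  expect_equal(nrow(filter_low_coverage(m, 100)), 0L)
  expect_equal(nrow(filter_low_coverage(m[0, , drop = FALSE], 10)), 0L)
  # "all samples below" variant keeps the row with one passing sample
  expect_equal(rownames(filter_low_coverage(m, 10, rule = "all")),
               c("a", "b", "c"))
})

test_that("low-coverage filtering is idempotent", {
  withr::with_seed(720, {
    for (rep in 1:20) {
      m <- matrix(rnbinom(60, mu = 12, size = 2), ncol = 3)
      rownames(m) <- paste0("f", seq_len(nrow(m)))
      once <- filter_low_coverage(m, 10)
      expect_identical(filter_low_coverage(once, 10), once)
    }
  })
})

test_that("size factors rescale totals by their geometric mean", {
  expect_equal(unname(size_factors_total_mapped(c(2e6, 2e6))), c(1, 1))
  expect_equal(unname(size_factors_total_mapped(c(1e6, 2e6))),
               c(1 / sqrt(2), sqrt(2)))
  expect_equal(unname(size_factors_total_mapped(5e6)), 1)
  expect_error(size_factors_total_mapped(c(1e6, 0)), "> 0")
  expect_equal(unname(size_factors_total_mapped(c(1e6, 2e6),
                                                reference_total = 1e6)),
               c(1, 2))
})

test_that("dispersion is method-of-moments with a Poisson floor", {
  # two samples with mean 10 and variance 30: alpha = (30 - 10) / 100
  g <- c(10 + sqrt(15), 10 - sqrt(15))
  m <- matrix(g, nrow = 1)
  expect_equal(estimate_dispersion(m, c("a", "a")), 0.2)
  # variance <= mean floors at alpha_min
  expect_equal(estimate_dispersion(matrix(c(10, 10), 1), c("a", "a")), 1e-8)
  expect_equal(estimate_dispersion(matrix(c(0, 0), 1), c("a", "a")), 1e-8)
  expect_error(estimate_dispersion(matrix(1:2, 1), c("a", "b")),
               ">= 2 samples")
})

test_that("dispersion estimates recover the simulation truth at 50 replicates", {
  withr::with_seed(721, {
    m <- matrix(rnbinom(1000 * 50, mu = 50, size = 1 / 0.1), nrow = 1000)
    a <- estimate_dispersion(m, rep("a", 50))
    expect_gte(mean(a >= 0.05 & a <= 0.15), 0.9)
  })
})

test_that("the NB Wald test matches hand cases and recovers planted enrichment", {
  # identical counts in both groups: no change, p = 1
  m <- matrix(rep(c(20, 30, 25), 2), nrow = 1)
  res <- nb_wald_test(m, rep(c("ref", "trt"), each = 3), "ref")
  expect_equal(res$log2fc, 0)
  expect_equal(res$pvalue, 1)

  # all-zero fragment: zero fold change, p = 1, no NaN
  res0 <- nb_wald_test(matrix(0, 1, 6), rep(c("ref", "trt"), each = 3), "ref")
  expect_equal(res0$log2fc, 0)
  expect_equal(res0$pvalue, 1)

  withr::with_seed(722, {
    mu <- matrix(25, 2000, 6)
    mu[, 4:6] <- 100
    m <- matrix(rnbinom(length(mu), mu = mu, size = 1 / 0.05), 2000)
    rownames(m) <- paste0("f", 1:2000)
    res <- nb_wald_test(m, rep(c("ref", "trt"), each = 3), "ref")
    expect_gt(mean(res$log2fc), 1.8)
    expect_lt(mean(res$log2fc), 2.2)
  })
})

test_that("Wald p-values agree with a numeric likelihood-ratio oracle", {
  # same known dispersion on both routes, 8 replicates per group: in this
  # regime the Wald and LRT p-values of the single-fragment comparison
  # track each other closely
  withr::with_seed(723, {
    for (mu_trt in c(50, 65, 80)) {
      for (rep in 1:5) {
        x <- rnbinom(16, mu = rep(c(50, mu_trt), each = 8), size = 1 / 0.05)
        m <- matrix(x, nrow = 1)
        p_wald <- nb_wald_test(m, rep(c("ref", "trt"), each = 8), "ref",
                               dispersion = 0.05)$pvalue
        p_lrt <- nb_lrt_pvalue_fixed_alpha(x[1:8], x[9:16], alpha = 0.05)
        expect_lt(abs(p_wald - p_lrt), 0.05)
      }
    }
  })
})

test_that("BH adjustment matches hand computation and propagates NaN", {
  expect_equal(bh_adjust(0.03), 0.03)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(rep(1, 5)), rep(1, 5))
  out <- bh_adjust(c(0.01, NaN, 0.02))
  expect_true(is.nan(out[2]))
  expect_equal(out[c(1, 3)], c(0.02, 0.02))
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("RPKM follows counts / (kb * millions) and scales with totals", {
  m <- matrix(c(10, 0), nrow = 2)
  r <- rpkm(m, lengths = c(1000, 500), totals = 1e6)
  expect_equal(r[, 1], c(10, 0))
  expect_equal(rpkm(m, c(1000, 500), 2e6), r / 2)
})

test_that("rescaling one library's counts and total leaves results unchanged", {
  withr::with_seed(724, {
    m <- matrix(rnbinom(400 * 6, mu = 40, size = 10), 400)
    rownames(m) <- paste0("f", 1:400)
    totals <- c(1e6, 1.5e6, 2e6, 1e6, 1.2e6, 1.8e6)
    group <- rep(c("ref", "trt"), each = 3)
    base <- nb_wald_test(m, group, "ref",
                         size_factors_total_mapped(totals, reference_total = 1e6))
    m2 <- m; m2[, 1] <- m2[, 1] * 7
    totals2 <- totals; totals2[1] <- totals2[1] * 7
    scaled <- nb_wald_test(m2, group, "ref",
                           size_factors_total_mapped(totals2, reference_total = 1e6))
    expect_equal(scaled$log2fc, base$log2fc, tolerance = 1e-9)
    expect_equal(scaled$pvalue, base$pvalue, tolerance = 1e-9)
  })
})
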