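fake_results <- function(log2fc, padj) {
  data.frame(fragment = paste0("f", seq_along(log2fc)), baseMean = 50,
             log2fc = log2fc, se = 0.3, pvalue = padj, padj = padj,
             stringsAsFactors = FALSE)
}

test_that("peak calling requires positive fold change and padj below alpha", {
  res <- fake_results(c(2, 2, -2, 0.5), c(0.01, 0.5, 0.01, 0.09))
  expect_equal(nrow(call_peaks(fake_results(c(1, 1), c(1, 1)))), 0L)
  peaks <- call_peaks(res, alpha = 0.1)
  expect_equal(peaks$fragment, c("f1", "f4"))
  expect_equal(call_peaks(res, alpha = 0.1, direction = "decreased")$fragment,
               "f3")
})

test_that("peak calling is monotone in alpha", {
  withr::with_seed(730, {
    res <- fake_results(rnorm(500), runif(500))
    alphas <- sort(runif(5))
    for (i in seq_len(length(alphas) - 1L)) {
      a <- call_peaks(res, alphas[i])$fragment
      b <- call_peaks(res, alphas[i + 1])$fragment
      expect_true(all(a %in% b))
    }
  })
})

test_that("negative intervals are drawn from length strata of the positives", {
  frags <- data.frame(contig = "chr",
                      start = c(0L, cumsum(c(rep(1000L, 20), rep(10000L, 20)))),
                      stringsAsFactors = FALSE)
  frags$end <- c(frags$start[-1], frags$start[nrow(frags)] + 1000L)
  frags <- frags[frags$end - frags$start > 0, ]
  frags$id <- sprintf("f%02d", seq_len(nrow(frags)))
  short_ids <- frags$id[frags$end - frags$start == 1000L]
  positives <- short_ids[1:10]

  expect_equal(nrow(select_negative_intervals(frags, positives, 0, seed = 1)), 0L)

  neg <- select_negative_intervals(frags, positives, 8, seed = 1)
  expect_equal(nrow(neg), 8L)
  # positives are all 1 kb, so the selection stays in the 1-kb stratum
  expect_true(all(neg$end - neg$start == 1000L))
  expect_false(any(neg$id %in% positives))

  again <- select_negative_intervals(frags, positives, 8, seed = 1)
  expect_identical(neg, again)
  other <- select_negative_intervals(frags, positives, 8, seed = 2)
  expect_false(identical(neg$id, other$id))

  # demanding more than the stratum holds borrows from the nearest one
  expect_warning(
    big <- select_negative_intervals(frags, positives, 15, seed = 3),
    "borrowing")
  expect_equal(nrow(big), 15L)
})

diff_sim <- function(seed, n_frag = 1000L, induced_fraction = 0.05) {
  frags <- data.frame(contig = "chr",
                      start = seq(0L, by = 2000L, length.out = n_frag))
  frags$end <- frags$start + 2000L
  frags$id <- sprintf("f%04d", seq_len(n_frag))
  cfg <- simulation_config(seed = seed, enriched_fraction = 1,
                           enrichment_log2fc = 0,
                           induced_fraction = induced_fraction,
                           induction_log2fc = 2)
  sim <- simulate_drip_counts(frags, cfg)
  sim
}

test_that("differential calling recovers planted induction and respects consistency", {
  sim <- diff_sim(731)
  dd <- call_differential_peaks(sim$counts, sim$meta, "mock", "E2_2h")
  planted <- sim$truth$fragment[sim$truth$induced]
  expect_gte(overlap_fraction(planted, dd$induced$fragment), 0.8)
  # with no planted effect almost nothing is called: the 3 vs 3 plug-in
  # Wald test leaves a small anti-conservative left tail (about half a
  # percent of null fragments after the consistency rule), so the null
  # call rate is bounded rather than exactly zero
  null_counts <- vapply(1:20, function(i) {
    s <- diff_sim(7310 + i, induced_fraction = 0)
    nrow(call_differential_peaks(s$counts, s$meta, "mock", "E2_2h")$induced)
  }, numeric(1))
  expect_lte(median(null_counts), 10)
})

test_that("the consistency rule only ever removes calls", {
  sim <- diff_sim(732)
  strict <- call_differential_peaks(sim$counts, sim$meta, "mock", "E2_2h",
                                    differential_call_config())
  loose <- call_differential_peaks(
    sim$counts, sim$meta, "mock", "E2_2h",
    differential_call_config(require_replicate_consistency = FALSE))
  expect_true(all(strict$induced$fragment %in% loose$induced$fragment))

  # force one replicate pair negative for a jointly significant region
  m <- sim$counts
  ip_mock_r1 <- sim$meta$sample_id[sim$meta$condition == "mock" &
                                     sim$meta$assay == "IP" &
                                     sim$meta$replicate == 1L]
  ip_e2_r1 <- sim$meta$sample_id[sim$meta$condition == "E2_2h" &
                                   sim$meta$assay == "IP" &
                                   sim$meta$replicate == 1L]
  target <- loose$induced$fragment[1]
  m[target, ip_mock_r1] <- 10000
  m[target, ip_e2_r1] <- 100
  strict2 <- call_differential_peaks(m, sim$meta, "mock", "E2_2h",
                                     differential_call_config())
  loose2 <- call_differential_peaks(
    m, sim$meta, "mock", "E2_2h",
    differential_call_config(require_replicate_consistency = FALSE))
  expect_false(target %in% strict2$induced$fragment)
  joint <- loose2$results[loose2$results$fragment == target, ]
  if (joint$log2fc > 0 && joint$padj < 0.1)
    expect_true(target %in% loose2$induced$fragment)
})

test_that("overlap fraction is intersection over the first set", {
  expect_equal(overlap_fraction(letters[1:10], letters[1:10]), 1)
  expect_equal(overlap_fraction(letters[1:5], letters[6:10]), 0)
  expect_equal(overlap_fraction(letters[1:10], letters[5:20]), 0.6)
  expect_warning(z <- overlap_fraction(character(0), "a"), "empty")
  expect_equal(z, 0)
})

test_that("peaks are assigned to the nearest gene within 1 kb of the body", {
  genes <- data.frame(contig = "chr", start = c(5000L, 20000L),
                      end = c(9000L, 30000L), gene = c("geneA", "geneB"),
                      stringsAsFactors = FALSE)
  peak <- function(s, e) data.frame(contig = "chr", start = s, end = e,
                                    id = "p1", stringsAsFactors = FALSE)
  inside <- assign_to_genes(peak(6000L, 7000L), genes)
  expect_equal(inside$gene, "geneA")
  expect_equal(inside$distance, 0)
  # peak ending 999 bp upstream of the gene start is assigned
  expect_equal(assign_to_genes(peak(3000L, 4001L), genes)$gene, "geneA")
  # 1001 bp away is not
  expect_equal(nrow(assign_to_genes(peak(3000L, 3999L), genes)), 0L)
  # equidistant between two genes: lexicographically smaller id wins
  mid <- assign_to_genes(peak(9500L, 19500L),
                         rbind(genes, data.frame(contig = "chr", start = 1000L,
                                                 end = 9000L, gene = "geneC")))
  expect_equal(mid$gene, "geneA")
})

test_that("meta-gene profiles are flat under uniform coverage and peak at a TSS spike", {
  genes <- data.frame(contig = "chr", start = c(10000L, 40000L),
                      end = c(16000L, 52000L), gene = c("g1", "g2"),
                      strand = c("+", "-"), stringsAsFactors = FALSE)
  flat <- data.frame(contig = "chr", start = 0L, end = 100000L, value = 2.5)
  prof <- metagene_profile(flat, genes, flank = 2000, body_bins = 50,
                           flank_bins = 10)
  expect_equal(nrow(prof), 70L)
  expect_true(all(abs(prof$mean - 2.5) < 1e-9))

  # delta spike at every TSS maximises the first body bin
  tss <- data.frame(contig = "chr",
                    start = c(10000L, 51999L), end = c(10001L, 52000L),
                    value = 1000)
  spiked <- metagene_profile(tss, genes, flank = 2000, body_bins = 50,
                             flank_bins = 10)
  expect_equal(which.max(spiked$mean), 11L)
  expect_equal(spiked$region[11], "body")

  zero <- data.frame(contig = "chr", start = 0L, end = 100000L, value = 0)
  expect_true(all(metagene_profile(zero, genes)$mean == 0))
})

test_that("mirroring the genome and strands reverses the meta-gene profile", {
  withr::with_seed(733, {
    L <- 50000L
    cov <- data.frame(contig = "chr", start = seq(0L, L - 500L, by = 500L))
    cov$end <- cov$start + 500L
    cov$value <- round(runif(nrow(cov)) * 10, 2)
    genes <- data.frame(contig = "chr", start = c(8000L, 30000L),
                        end = c(15000L, 41000L), gene = c("g1", "g2"),
                        strand = c("+", "-"), stringsAsFactors = FALSE)
    mirror_cov <- data.frame(contig = "chr", start = L - cov$end,
                             end = L - cov$start, value = cov$value)
    mirror_genes <- data.frame(contig = "chr", start = L - genes$end,
                               end = L - genes$start, gene = genes$gene,
                               strand = c("-", "+"), stringsAsFactors = FALSE)
    p1 <- metagene_profile(cov, genes, flank = 2000, body_bins = 40,
                           flank_bins = 8)
    p2 <- metagene_profile(mirror_cov, mirror_genes, flank = 2000,
                           body_bins = 40, flank_bins = 8)
    expect_equal(p2$mean, p1$mean, tolerance = 1e-9)
  })
})
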