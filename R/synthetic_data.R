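#' Configuration of the synthetic DRIP-seq study
#'
#' Defines the generative model used to exercise every stage of the
#' pipeline without external data: a random genome with planted
#' restriction sites, negative-binomial fragment counts with planted
#' IP-over-input enrichment and estrogen induction, a gene table with
#' correlated expression/replication-timing covariates and planted induced
#' genes, and mutation sets placed with configurable odds in induced
#' genes.  The defaults are the package's reference study conditions; the
#' methods vignette discusses how they were chosen and what they do and do
#' not emulate.
#'
#' @param seed integer seed; mandatory.  All randomness in the generator
#'   flows from it through isolated RNG scopes, so a seed fixes every
#'   downstream artifact byte for byte.
#' @param n_contigs,contig_length genome shape (default 2 x 50 kb).
#' @param planted_sites_per_kb planted restriction sites per enzyme per kb
#'   (default 0.25, i.e. one per 4 kb, on top of background occurrences).
#' @param input_mean NB mean of input-library fragment counts (default 50).
#' @param dispersion NB dispersion `alpha` (variance `mu + alpha mu^2`;
#'   default 0.05).
#' @param enriched_fraction fraction of fragments with planted
#'   IP-over-input enrichment (default 0.10).
#' @param enrichment_log2fc planted IP enrichment effect (default 2).
#' @param induced_fraction fraction of fragments (drawn from the enriched
#'   ones) with additional planted E2 induction (default 0.05).
#' @param induction_log2fc planted induction effect in E2 IP libraries
#'   (default 2).
#' @param replicates biological replicates per condition (default 3).
#' @param conditions condition labels (default `c("mock", "E2_2h")`;
#'   conditions starting with `"E2"` receive the induction effect).
#' @param total_reads_meanlog,total_reads_sdlog log-normal model of
#'   per-library total mapped reads (default median 2e6, sdlog 0.15).
#' @param n_genes number of genes in the expression panel (default 3000).
#' @param induced_gene_fraction fraction of genes planted as E2-induced
#'   (default 0.25).
#' @param z_threshold,z_margin induced genes get a true z-score at least
#'   `z_threshold + z_margin` (defaults 2 and 1); non-induced genes stay
#'   strictly below `z_threshold`.
#' @param covariate_cor target correlation between log mean expression and
#'   replication timing (default 0.6).
#' @param expr_meanlog,expr_sdlog log-normal model of mock expression
#'   (defaults 3 and 1, arbitrary expression units).
#' @param length_meanlog,length_sdlog log-normal model of gene length in
#'   bp (defaults `log(1e4)` and 0.6: median 10 kb).
#' @param sv_prob,translocation_prob baseline per-gene probability of
#'   carrying at least one structural variant / translocation in any
#'   patient (defaults 0.3 and 0.2).
#' @param mutation_odds odds multiplier for mutation presence in induced
#'   genes (default 3; 1 means no planted enrichment).
#' @param ssm_rate_per_kb baseline simple-somatic-mutation rate per kb
#'   (default 2).
#' @param ssm_induced_multiplier rate multiplier for induced genes
#'   (default 1/3: planted depletion, mirroring the direction reported for
#'   simple somatic mutations).
#' @return a validated list of class `drip_sim_config`.
#' @export
simulation_config <- function(seed,
                              n_contigs = 2L, contig_length = 50000L,
                              planted_sites_per_kb = 0.25,
                              input_mean = 50, dispersion = 0.05,
                              enriched_fraction = 0.10, enrichment_log2fc = 2,
                              induced_fraction = 0.05, induction_log2fc = 2,
                              replicates = 3L,
                              conditions = c("mock", "E2_2h"),
                              total_reads_meanlog = log(2e6),
                              total_reads_sdlog = 0.15,
                              n_genes = 3000L, induced_gene_fraction = 0.25,
                              z_threshold = 2, z_margin = 1,
                              covariate_cor = 0.6,
                              expr_meanlog = 3, expr_sdlog = 1,
                              length_meanlog = log(1e4), length_sdlog = 0.6,
                              sv_prob = 0.3, translocation_prob = 0.2,
                              mutation_odds = 3,
                              ssm_rate_per_kb = 2,
                              ssm_induced_multiplier = 1 / 3) {
  if (missing(seed)) stop("seed is mandatory")
  cfg <- list(seed = as.integer(seed), n_contigs = as.integer(n_contigs),
              contig_length = as.integer(contig_length),
              planted_sites_per_kb = planted_sites_per_kb,
              input_mean = input_mean, dispersion = dispersion,
              enriched_fraction = enriched_fraction,
              enrichment_log2fc = enrichment_log2fc,
              induced_fraction = induced_fraction,
              induction_log2fc = induction_log2fc,
              replicates = as.integer(replicates), conditions = conditions,
              total_reads_meanlog = total_reads_meanlog,
              total_reads_sdlog = total_reads_sdlog,
              n_genes = as.integer(n_genes),
              induced_gene_fraction = induced_gene_fraction,
              z_threshold = z_threshold, z_margin = z_margin,
              covariate_cor = covariate_cor,
              expr_meanlog = expr_meanlog, expr_sdlog = expr_sdlog,
              length_meanlog = length_meanlog, length_sdlog = length_sdlog,
              sv_prob = sv_prob, translocation_prob = translocation_prob,
              mutation_odds = mutation_odds,
              ssm_rate_per_kb = ssm_rate_per_kb,
              ssm_induced_multiplier = ssm_induced_multiplier)
  fracs <- c(cfg$enriched_fraction, cfg$induced_fraction,
             cfg$induced_gene_fraction, cfg$sv_prob, cfg$translocation_prob)
  stopifnot(all(fracs >= 0 & fracs <= 1),
            cfg$induced_fraction <= cfg$enriched_fraction,
            all(is.finite(c(cfg$enrichment_log2fc, cfg$induction_log2fc))),
            cfg$dispersion >= 0, cfg$input_mean > 0,
            abs(cfg$covariate_cor) <= 1, cfg$mutation_odds > 0,
            cfg$replicates >= 1L, length(cfg$conditions) >= 2L)
  structure(cfg, class = "drip_sim_config")
}

# distinct RNG scopes per artifact so each simulate_* call is individually
# reproducible from the one configured seed
sim_seed <- function(cfg, offset) {
  s <- (as.double(cfg$seed) + 77003 * offset) %% 2147483647
  as.integer(s)
}

#' Simulate a genome with planted restriction sites
#'
#' Draws uniform-random A/C/G/T contigs, then overwrites non-overlapping
#' positions with enzyme recognition sequences at the configured planted
#' density.  Random background occurrences of the recognition sequences
#' arise on top of the planted ones; the truth table therefore lists the
#' planted sites only, and every planted site is recoverable by
#' [find_restriction_sites()].
#'
#' @param cfg a [simulation_config()].
#' @param enzymes enzyme table (default [drip_enzymes()]).
#' @return list with `genome` (named character vector) and `planted_sites`
#'   (data.frame `contig`, `position`, `enzyme`, `cut_position`).
#' @export
simulate_genome <- function(cfg, enzymes = drip_enzymes()) {
  stopifnot(inherits(cfg, "drip_sim_config"))
  enzymes <- resolve_enzymes(enzymes)
  withr::with_seed(sim_seed(cfg, 1L), {
    genome <- character(cfg$n_contigs)
    names(genome) <- sprintf("ctg%02d", seq_len(cfg$n_contigs))
    truth <- list()
    for (i in seq_len(cfg$n_contigs)) {
      L <- cfg$contig_length
      seq_chars <- sample(c("A", "C", "G", "T"), L, replace = TRUE)
      n_per_enzyme <- round(cfg$planted_sites_per_kb * L / 1000)
      n_plant <- n_per_enzyme * nrow(enzymes)
      if (n_plant > 0) {
        width <- max(nchar(enzymes$recognition))
        cand <- sort(sample.int(L - width, min(4L * n_plant, L - width)))
        keep <- c(TRUE, diff(cand) >= width)
        cand <- cand[keep][seq_len(min(n_plant, sum(keep)))]
        enz_idx <- rep(seq_len(nrow(enzymes)), length.out = length(cand))
        enz_idx <- sample(enz_idx)
        for (j in seq_along(cand)) {
          rec <- strsplit(enzymes$recognition[enz_idx[j]], "")[[1]]
          seq_chars[cand[j]:(cand[j] + length(rec) - 1L)] <- rec
        }
        truth[[i]] <- data.frame(
          contig = names(genome)[i],
          position = cand - 1L,
          enzyme = enzymes$name[enz_idx],
          cut_position = cand - 1L + enzymes$cut_offset[enz_idx],
          stringsAsFactors = FALSE)
      }
      genome[i] <- paste(seq_chars, collapse = "")
    }
    truth <- do.call(rbind, truth)
    if (!is.null(truth)) {
      truth <- truth[order(truth$contig, truth$position), , drop = FALSE]
      rownames(truth) <- NULL
    }
    list(genome = genome, planted_sites = truth)
  })
}

#' Simulate DRIP-seq fragment counts with planted effects
#'
#' Counts are negative binomial with variance `mu + alpha mu^2`.  The
#' expected count of fragment `f` in sample `s` is the input mean scaled
#' by the sample's size factor, multiplied by `2^enrichment_log2fc` in IP
#' libraries for planted-enriched fragments, and additionally by
#' `2^induction_log2fc` in E2-condition IP libraries for planted-induced
#' fragments (induced fragments are a subset of the enriched ones).
#'
#' @param fragments data.frame as from [digest_to_fragments()].
#' @param cfg a [simulation_config()].
#' @return list with `counts` (matrix, fragments x samples), `meta`
#'   (sample sheet), `size_factors`, and `truth` (data.frame `fragment`,
#'   `enriched`, `induced`).
#' @export
simulate_drip_counts <- function(fragments, cfg) {
  stopifnot(inherits(cfg, "drip_sim_config"))
  withr::with_seed(sim_seed(cfg, 2L), {
    design <- expand.grid(replicate = seq_len(cfg$replicates),
                          assay = c("IP", "input"),
                          condition = cfg$conditions,
                          stringsAsFactors = FALSE)
    design <- design[c("condition", "assay", "replicate")]
    meta <- sample_sheet(
      sample_id = sprintf("%s_%s_r%d", design$condition, design$assay,
                          design$replicate),
      condition = design$condition, assay = design$assay,
      replicate = design$replicate,
      total_mapped_reads = round(rlnorm(nrow(design), cfg$total_reads_meanlog,
                                        cfg$total_reads_sdlog)))
    sf <- size_factors_total_mapped(meta)
    nf <- nrow(fragments)
    enriched <- rep(FALSE, nf)
    enriched[sample.int(nf, round(cfg$enriched_fraction * nf))] <- TRUE
    induced <- rep(FALSE, nf)
    n_ind <- round(cfg$induced_fraction * nf)
    if (n_ind > 0)
      induced[sample(which(enriched), n_ind)] <- TRUE
    mu <- matrix(cfg$input_mean, nf, nrow(meta),
                 dimnames = list(fragments$id, meta$sample_id))
    mu <- sweep(mu, 2L, sf, "*")
    ip <- meta$assay == "IP"
    e2 <- startsWith(meta$condition, "E2")
    mu[enriched, ip] <- mu[enriched, ip] * 2^cfg$enrichment_log2fc
    mu[induced, ip & e2] <- mu[induced, ip & e2] * 2^cfg$induction_log2fc
    size <- if (cfg$dispersion > 0) 1 / cfg$dispersion else Inf
    counts <- matrix(rnbinom(length(mu), mu = mu, size = size),
                     nf, nrow(meta), dimnames = dimnames(mu))
    list(counts = counts, meta = meta, size_factors = sf,
         truth = data.frame(fragment = fragments$id, enriched = enriched,
                            induced = induced, stringsAsFactors = FALSE))
  })
}

#' Expand fragment counts into read 5'-position intervals
#'
#' Inverts counting for testing purposes: for each fragment, draws the
#' counted number of read 5' positions uniformly within the fragment and
#' returns them as 1-bp BED intervals.  [count_reads_to_fragments()]
#' recovers the input counts exactly.
#'
#' @param fragments data.frame as from [digest_to_fragments()].
#' @param counts integer vector of counts named by fragment id.
#' @param seed integer seed.
#' @return data.frame with `contig`, `start`, `end`, `name`, `score`,
#'   `strand`.
#' @export
simulate_reads <- function(fragments, counts, seed) {
  stopifnot(all(names(counts) %in% fragments$id))
  counts <- counts[fragments$id]
  counts[is.na(counts)] <- 0L
  withr::with_seed(as.integer(seed), {
    idx <- rep(seq_len(nrow(fragments)), counts)
    width <- fragments$end[idx] - fragments$start[idx]
    pos <- fragments$start[idx] + floor(runif(length(idx)) * width)
    data.frame(contig = fragments$contig[idx], start = as.integer(pos),
               end = as.integer(pos) + 1L, name = ".", score = 0L,
               strand = "+", stringsAsFactors = FALSE)
  })
}

#' Simulate a gene expression panel with planted E2 induction
#'
#' Mock expression is log-normal; per-condition standard deviations come
#' from a gamma coefficient-of-variation model.  Each planted induced gene
#' has its E2 mean shifted so that its true z-score
#' ([e2_zscore()]) lands at least `z_margin` above `z_threshold`;
#' non-induced genes stay strictly below the threshold.  Mean expression
#' is averaged over mock, an early-E2 and a late-E2 condition (the late
#' mean relaxes halfway back to mock), and replication timing is drawn
#' correlated with log mean expression at the configured correlation
#' (arbitrary units; early-replicating genes score high).
#'
#' @param cfg a [simulation_config()].
#' @return list with `genes` (data.frame `gene`, `mu_mock`, `sd_mock`,
#'   `mu_e2`, `sd_e2`, `length_bp`, `repli_timing`, `mean_expr`, `z`,
#'   `class`) and `truth` (data.frame `gene`, `planted_induced`).
#' @export
simulate_gene_table <- function(cfg) {
  stopifnot(inherits(cfg, "drip_sim_config"))
  withr::with_seed(sim_seed(cfg, 3L), {
    n <- cfg$n_genes
    gene <- sprintf("gene%05d", seq_len(n))
    mu_mock <- rlnorm(n, cfg$expr_meanlog, cfg$expr_sdlog)
    cv_mock <- rgamma(n, shape = 4, rate = 20) + 0.05
    cv_e2 <- rgamma(n, shape = 4, rate = 20) + 0.05
    sd_mock <- mu_mock * cv_mock
    planted <- rep(FALSE, n)
    planted[sample.int(n, round(cfg$induced_gene_fraction * n))] <- TRUE
    z_target <- ifelse(planted,
                       cfg$z_threshold + cfg$z_margin + rexp(n, rate = 1),
                       pmin(rnorm(n, 0, 0.8), cfg$z_threshold - 0.25))
    sd_e2 <- mu_mock * cv_e2
    mu_e2 <- mu_mock + z_target * sqrt(sd_mock^2 + sd_e2^2)
    mu_e2 <- pmax(mu_e2, 0.05 * mu_mock)
    mu_e2_late <- mu_mock + 0.5 * (mu_e2 - mu_mock)
    mean_expr <- (mu_mock + mu_e2 + mu_e2_late) / 3
    le <- studentize(log(mean_expr))
    rho <- cfg$covariate_cor
    repli_timing <- rho * le + sqrt(1 - rho^2) * rnorm(n)
    length_bp <- pmax(round(rlnorm(n, cfg$length_meanlog, cfg$length_sdlog)),
                      200L)
    z <- e2_zscore(mu_mock, sd_mock, mu_e2, sd_e2)
    genes <- data.frame(gene = gene, mu_mock = mu_mock, sd_mock = sd_mock,
                        mu_e2 = mu_e2, sd_e2 = sd_e2, length_bp = length_bp,
                        repli_timing = repli_timing, mean_expr = mean_expr,
                        z = z, class = classify_induced(z, cfg$z_threshold),
                        stringsAsFactors = FALSE)
    list(genes = genes,
         truth = data.frame(gene = gene, planted_induced = planted,
                            stringsAsFactors = FALSE))
  })
}

#' Simulate breast-cancer-style mutation sets
#'
#' For the presence classes (structural variants, translocations) each
#' gene carries at least one event with its baseline probability, with the
#' odds multiplied by `mutation_odds` for planted induced genes.  Simple
#' somatic mutation counts are Poisson with mean
#' `length_kb * ssm_rate_per_kb`, multiplied by `ssm_induced_multiplier`
#' for induced genes.
#'
#' @param genes gene table from [simulate_gene_table()].
#' @param truth truth table from [simulate_gene_table()] (planted
#'   induction labels drive the planted mutation effects).
#' @param cfg a [simulation_config()].
#' @return data.frame with `gene`, `class`, `count` (rows with
#'   `count >= 1` only).
#' @export
simulate_mutations <- function(genes, truth, cfg) {
  stopifnot(inherits(cfg, "drip_sim_config"),
            identical(genes$gene, truth$gene))
  withr::with_seed(sim_seed(cfg, 4L), {
    n <- nrow(genes)
    ind <- truth$planted_induced
    presence <- function(p0, class) {
      p <- plogis(qlogis(p0) + log(cfg$mutation_odds) * ind)
      hit <- rbinom(n, 1L, p) == 1L
      if (!any(hit)) return(NULL)
      data.frame(gene = genes$gene[hit], class = class, count = 1L,
                 stringsAsFactors = FALSE)
    }
    lam <- genes$length_bp / 1000 * cfg$ssm_rate_per_kb *
      ifelse(ind, cfg$ssm_induced_multiplier, 1)
    ssm <- rpois(n, lam)
    out <- rbind(presence(cfg$sv_prob, "structural_variant"),
                 presence(cfg$translocation_prob, "translocation"),
                 if (any(ssm > 0))
                   data.frame(gene = genes$gene[ssm > 0],
                              class = "simple_somatic",
                              count = ssm[ssm > 0], stringsAsFactors = FALSE))
    rownames(out) <- NULL
    out
  })
}

#' Simulate a complete dataset on disk
#'
#' Generates every input the pipeline consumes and writes it to a
#' directory: `genome.fa`, `fragments.bed` (digest of the simulated
#' genome with the standard cocktail), `samples.tsv`, `counts.tsv`,
#' `genes.tsv`, `mutations.tsv`, truth tables
#' (`truth_sites.tsv`, `truth_fragments.tsv`, `truth_genes.tsv`) and a
#' `config.yaml` echo of the configuration.  Byte-identical across runs
#' with the same configuration.
#'
#' @param cfg a [simulation_config()].
#' @param dir output directory (created if needed).
#' @return the directory path, invisibly.
#' @export
simulate_dataset <- function(cfg, dir) {
  stopifnot(inherits(cfg, "drip_sim_config"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  gen <- simulate_genome(cfg)
  dig <- digest_genome(gen$genome)
  cnt <- simulate_drip_counts(dig$fragments, cfg)
  gt <- simulate_gene_table(cfg)
  mut <- simulate_mutations(gt$genes, gt$truth, cfg)
  prov <- function(what) provenance_lines(what, list(seed = cfg$seed))
  write_fasta(gen$genome, file.path(dir, "genome.fa"))
  frags <- dig$fragments
  frags$name <- frags$id
  write_bed(frags, file.path(dir, "fragments.bed"), prov("simulate/fragments"))
  write_tsv(cnt$meta, file.path(dir, "samples.tsv"), prov("simulate/samples"))
  counts_df <- data.frame(fragment = rownames(cnt$counts), cnt$counts,
                          check.names = FALSE, stringsAsFactors = FALSE)
  write_tsv(counts_df, file.path(dir, "counts.tsv"), prov("simulate/counts"))
  write_tsv(gt$genes, file.path(dir, "genes.tsv"), prov("simulate/genes"))
  write_tsv(mut, file.path(dir, "mutations.tsv"), prov("simulate/mutations"))
  write_tsv(gen$planted_sites, file.path(dir, "truth_sites.tsv"),
            prov("simulate/truth"))
  write_tsv(cnt$truth, file.path(dir, "truth_fragments.tsv"),
            prov("simulate/truth"))
  write_tsv(gt$truth, file.path(dir, "truth_genes.tsv"), prov("simulate/truth"))
  writeLines(yaml::as.yaml(unclass(cfg)), file.path(dir, "config.yaml"))
  invisible(dir)
}
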