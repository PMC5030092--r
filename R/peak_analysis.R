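#' Configuration for differential peak calling
#'
#' @param alpha adjusted-p threshold for a differential call (default 0.1,
#'   the threshold used for induced DRIP peaks).
#' @param require_replicate_consistency if `TRUE` (default), an induced
#'   (decreased) call additionally requires a positive (negative)
#'   fold change in every per-replicate mock/treatment pair.  Consistency
#'   is a sign requirement, not a per-replicate significance requirement:
#'   a single replicate pair carries no dispersion estimate of its own.
#' @param negative_set_size_ratio size of the negative interval set
#'   relative to the positive set (used by callers assembling the
#'   combined region set).
#' @return a list of class `drip_diff_config`.
#' @export
differential_call_config <- function(alpha = 0.1,
                                     require_replicate_consistency = TRUE,
                                     negative_set_size_ratio = 1) {
  stopifnot(alpha > 0, alpha <= 1, negative_set_size_ratio >= 0)
  structure(list(alpha = alpha,
                 require_replicate_consistency = require_replicate_consistency,
                 negative_set_size_ratio = negative_set_size_ratio),
            class = "drip_diff_config")
}

#' Call DRIP peaks from per-fragment test results
#'
#' A fragment is a peak when its IP-over-input (or treatment-over-
#' reference) fold change points in the requested direction and its
#' BH-adjusted p-value falls below `alpha`.  Calling is monotone in
#' `alpha`.
#'
#' @param results data.frame from [nb_wald_test()].
#' @param alpha adjusted-p threshold (default 0.1).
#' @param direction `"enriched"`/`"induced"` (log2fc > 0, default) or
#'   `"decreased"` (log2fc < 0).
#' @return the peak rows of `results`, with the calling rule recorded in
#'   attributes `alpha` and `direction`.
#' @export
call_peaks <- function(results, alpha = 0.1,
                       direction = c("enriched", "induced", "decreased")) {
  direction <- match.arg(direction)
  stopifnot(alpha > 0, alpha <= 1,
            all(c("fragment", "log2fc", "padj") %in% names(results)))
  sign_ok <- if (direction == "decreased") results$log2fc < 0 else results$log2fc > 0
  out <- results[!is.na(results$padj) & results$padj < alpha & sign_ok, ,
                 drop = FALSE]
  rownames(out) <- NULL
  attr(out, "alpha") <- alpha
  attr(out, "direction") <- direction
  out
}

#' Select length-matched negative intervals
#'
#' Builds the background set for differential calling: `n` fragments with
#' no significant enrichment whose length distribution matches the
#' positive set, by stratified sampling over the length deciles of the
#' positive fragments.  When a stratum has too few candidates the
#' shortfall is borrowed from the nearest stratum, with a warning.
#' Selection is deterministic given `seed`.
#'
#' @param fragments data.frame as from [digest_to_fragments()].
#' @param positive_ids ids of fragments called as peaks.
#' @param n number of negative intervals to select.
#' @param seed integer seed.
#' @param n_strata number of length strata (default 10, deciles).
#' @return the selected rows of `fragments`.
#' @export
select_negative_intervals <- function(fragments, positive_ids, n, seed,
                                      n_strata = 10L) {
  stopifnot(all(c("id", "start", "end") %in% names(fragments)), n >= 0)
  if (n == 0L) return(fragments[0L, , drop = FALSE])
  pos <- fragments[fragments$id %in% positive_ids, , drop = FALSE]
  cand <- fragments[!(fragments$id %in% positive_ids), , drop = FALSE]
  if (nrow(cand) < n) stop("not enough non-positive fragments")
  if (nrow(pos) == 0L) stop("no positive fragments to match lengths against")
  len_pos <- pos$end - pos$start
  len_cand <- cand$end - cand$start
  breaks <- unique(quantile(len_pos, probs = seq(0, 1, length.out = n_strata + 1)))
  if (length(breaks) == 1L) breaks <- rep(breaks, 2L)  # all positives equal
  k <- length(breaks) - 1L
  # stratum 0 marks lengths outside the positive range; such candidates
  # are only reachable by borrowing
  stratum <- function(l) {
    s <- pmin(pmax(findInterval(l, breaks, rightmost.closed = TRUE), 1L), k)
    s[l < breaks[1L] | l > breaks[k + 1L]] <- 0L
    s
  }
  s_pos <- stratum(len_pos)
  s_cand <- stratum(len_cand)
  want <- as.vector(round(n * tabulate(s_pos, k) / length(s_pos)))
  # rounding can leave a deficit/surplus; settle it on the largest stratum
  diff <- n - sum(want)
  if (diff != 0L) {
    i <- which.max(want)
    want[i] <- want[i] + diff
  }
  picked <- withr::with_seed(as.integer(seed), {
    picked <- character(0)
    short <- integer(0)
    for (s in seq_len(k)) {
      avail <- setdiff(cand$id[s_cand == s], picked)
      take <- min(want[s], length(avail))
      if (take > 0L)
        picked <- c(picked, sample(avail, take))
      if (take < want[s]) short <- c(short, rep(s, want[s] - take))
    }
    if (length(short)) {
      warning("insufficient candidates in ", length(unique(short)),
              " length stratum/strata; borrowing from nearest strata")
      mid <- (breaks[-1L] + breaks[-(k + 1L)]) / 2
      for (s in short) {
        got <- FALSE
        for (d in seq_len(k)) {
          near <- c(s - d, s + d)
          near <- near[near >= 1L & near <= k]
          avail <- setdiff(cand$id[s_cand %in% near], picked)
          if (length(avail)) {
            picked <- c(picked, sample(avail, 1L))
            got <- TRUE
            break
          }
        }
        if (!got) {
          # all in-range strata exhausted: take the out-of-range candidate
          # whose length is closest to the stratum centre
          avail <- setdiff(cand$id[s_cand == 0L], picked)
          if (!length(avail)) stop("not enough candidates to borrow from")
          l <- len_cand[match(avail, cand$id)]
          picked <- c(picked, avail[order(abs(l - mid[s]), avail)[1L]])
        }
      }
    }
    picked
  })
  out <- cand[match(picked, cand$id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Call hormone-induced differential DRIP peaks
#'
#' Runs the joint NB test ([nb_wald_test()]) on IP counts over a combined
#' region set (positives plus negatives) between two conditions, then
#' applies the calling rule of `config`: induced means log2fc > 0 and
#' padj < alpha, and (when replicate consistency is on) a positive
#' fold change in every per-replicate pair; decreased is symmetric.
#'
#' @param counts region x samples count matrix (IP libraries of the two
#'   conditions, or a larger matrix: relevant samples are selected via
#'   `meta`).
#' @param meta sample sheet ([sample_sheet()]) describing the columns of
#'   `counts`.
#' @param reference reference condition label (e.g. `"mock"`).
#' @param treatment treatment condition label (e.g. `"E2_2h"`).
#' @param config a [differential_call_config()].
#' @param size_factors optional per-sample factors for the *full* `counts`
#'   matrix; computed from `meta$total_mapped_reads` when `NULL`.
#' @param pseudo_mean pseudo-mean for per-replicate fold changes and the
#'   joint test.
#' @return list with `results` (joint test results plus a
#'   `replicate_consistent_up`/`_down` column), `induced` and `decreased`
#'   (peak data.frames as from [call_peaks()]).
#' @export
call_differential_peaks <- function(counts, meta, reference, treatment,
                                    config = differential_call_config(),
                                    size_factors = NULL, pseudo_mean = 0.5) {
  stopifnot(inherits(config, "drip_diff_config"),
            ncol(counts) == nrow(meta))
  if (is.null(size_factors)) size_factors <- size_factors_total_mapped(meta)
  sel <- meta$condition %in% c(reference, treatment) &
    (if ("assay" %in% names(meta)) meta$assay == "IP" else TRUE)
  m <- counts[, sel, drop = FALSE]
  meta <- meta[sel, , drop = FALSE]
  sf <- size_factors[sel]
  group <- meta$condition
  if (config$require_replicate_consistency) {
    reps <- intersect(meta$replicate[group == reference],
                      meta$replicate[group == treatment])
    if (length(reps) < 2L)
      stop("replicate consistency requires >= 2 paired replicates per condition")
  }
  res <- nb_wald_test(m, group, reference, size_factors = sf,
                      pseudo_mean = pseudo_mean)
  q <- normalize_counts(m, sf)
  reps <- intersect(meta$replicate[group == reference],
                    meta$replicate[group == treatment])
  rep_lfc <- vapply(reps, function(r) {
    jr <- which(group == reference & meta$replicate == r)[1]
    jt <- which(group == treatment & meta$replicate == r)[1]
    log2((q[, jt] + pseudo_mean) / (q[, jr] + pseudo_mean))
  }, numeric(nrow(m)))
  rep_lfc <- matrix(rep_lfc, nrow = nrow(m))
  res$replicate_consistent_up <- apply(rep_lfc > 0, 1L, all)
  res$replicate_consistent_down <- apply(rep_lfc < 0, 1L, all)
  induced <- call_peaks(res, config$alpha, "induced")
  decreased <- call_peaks(res, config$alpha, "decreased")
  if (config$require_replicate_consistency) {
    induced <- induced[induced$replicate_consistent_up, , drop = FALSE]
    decreased <- decreased[decreased$replicate_consistent_down, , drop = FALSE]
  }
  rownames(induced) <- rownames(decreased) <- NULL
  list(results = res, induced = induced, decreased = decreased)
}

#' Fraction of one peak set contained in another
#'
#' `|A intersect B| / |A|` by fragment id; 0 (with a warning) when `A` is
#' empty.
#'
#' @param a,b character vectors of fragment ids (or data.frames with a
#'   `fragment` column).
#' @return a single number in `[0, 1]`.
#' @export
overlap_fraction <- function(a, b) {
  if (is.data.frame(a)) a <- a$fragment
  if (is.data.frame(b)) b <- b$fragment
  a <- unique(a); b <- unique(b)
  if (length(a) == 0L) {
    warning("empty reference set; overlap fraction is 0")
    return(0)
  }
  sum(a %in% b) / length(a)
}

#' Assign peaks to nearby genes
#'
#' A peak is gene-proximal when its interval lies within, or within
#' `max_distance` of, a gene body (distance to the body, not the TSS).
#' Ties are broken by smaller distance, then lexicographically by gene id.
#'
#' @param peaks data.frame with `contig`, `start`, `end`, `id`.
#' @param genes data.frame with `contig`, `start`, `end`, `gene`.
#' @param max_distance maximum gap in bp (default 1000).
#' @return data.frame with `id`, `gene`, `distance` for assigned peaks
#'   only.
#' @export
assign_to_genes <- function(peaks, genes, max_distance = 1000) {
  stopifnot(all(c("contig", "start", "end", "id") %in% names(peaks)),
            all(c("contig", "start", "end", "gene") %in% names(genes)))
  out <- lapply(seq_len(nrow(peaks)), function(i) {
    g <- genes[genes$contig == peaks$contig[i], , drop = FALSE]
    if (nrow(g) == 0L) return(NULL)
    d <- pmax(g$start - peaks$end[i], peaks$start[i] - g$end, 0)
    ok <- d <= max_distance
    if (!any(ok)) return(NULL)
    g <- g[ok, , drop = FALSE]; d <- d[ok]
    j <- order(d, g$gene, method = "radix")[1L]
    data.frame(id = peaks$id[i], gene = g$gene[j], distance = d[j],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  if (is.null(out))
    out <- data.frame(id = character(0), gene = character(0),
                      distance = numeric(0))
  rownames(out) <- NULL
  out
}

# step-function coverage lookup built from a bedGraph data.frame;
# returns a function(contig, positions) -> per-base values (0 in gaps and
# outside the covered range)
coverage_lookup <- function(coverage) {
  stopifnot(all(c("contig", "start", "end", "value") %in% names(coverage)))
  parts <- split(coverage[c("start", "end", "value")], coverage$contig)
  parts <- lapply(parts, function(p) p[order(p$start), , drop = FALSE])
  function(contig, pos) {
    p <- parts[[contig]]
    if (is.null(p)) return(numeric(length(pos)))
    idx <- findInterval(pos, p$start)
    val <- numeric(length(pos))
    hit <- idx > 0L
    hit[hit] <- pos[hit] < p$end[idx[hit]]
    val[hit] <- p$value[idx[hit]]
    val
  }
}

#' Meta-gene coverage profile
#'
#' Averages a coverage track over genes on a common coordinate system:
#' a fixed 5' flank, the gene body rescaled to a fixed number of bins, and
#' a fixed 3' flank.  Minus-strand genes are reversed so that the profile
#' always reads 5' to 3'.  Each bin value is the mean per-base coverage in
#' the bin; flanks extending beyond the covered range contribute zeros.
#'
#' @param coverage bedGraph-style data.frame (`contig`, `start`, `end`,
#'   `value`), non-negative.
#' @param genes data.frame with `contig`, `start`, `end`, `gene`,
#'   `strand`.
#' @param flank flank size in bp (default 2000).
#' @param body_bins number of bins over the gene body (default 100).
#' @param flank_bins number of bins per flank (default 20).
#' @return data.frame with `bin` (1-based, 5' to 3'), `region`
#'   (`"flank5"`, `"body"`, `"flank3"`) and `mean` coverage.
#' @export
metagene_profile <- function(coverage, genes, flank = 2000L, body_bins = 100L,
                             flank_bins = 20L) {
  stopifnot(all(c("contig", "start", "end", "strand") %in% names(genes)),
            flank >= flank_bins, body_bins >= 1L, flank_bins >= 1L)
  lookup <- coverage_lookup(coverage)
  bin_means <- function(vals, nbins) {
    n <- length(vals)
    edges <- floor(seq(0L, n, length.out = nbins + 1L))
    vapply(seq_len(nbins), function(i) {
      lo <- edges[i] + 1L
      hi <- max(edges[i + 1L], lo)
      mean(vals[lo:min(hi, n)])
    }, numeric(1))
  }
  profs <- vapply(seq_len(nrow(genes)), function(i) {
    ctg <- genes$contig[i]
    s <- genes$start[i]; e <- genes$end[i]
    left <- lookup(ctg, seq.int(s - flank, s - 1L))
    body <- lookup(ctg, seq.int(s, e - 1L))
    right <- lookup(ctg, seq.int(e, e + flank - 1L))
    v <- c(bin_means(left, flank_bins), bin_means(body, body_bins),
           bin_means(right, flank_bins))
    if (genes$strand[i] == "-") rev(v) else v
  }, numeric(2L * flank_bins + body_bins))
  profs <- matrix(profs, nrow = 2L * flank_bins + body_bins)
  data.frame(bin = seq_len(nrow(profs)),
             region = rep(c("flank5", "body", "flank3"),
                          c(flank_bins, body_bins, flank_bins)),
             mean = rowMeans(profs))
}
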