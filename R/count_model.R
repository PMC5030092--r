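#' Build and validate a sample sheet
#'
#' A DRIP-seq design is described by one row per sequencing library:
#' the treatment condition (e.g. `mock`, `E2_2h`, `E2_24h`), whether the
#' library is the S9.6 immunoprecipitate (`IP`) or its `input`, the
#' biological replicate, and the library's total mapped reads used for
#' normalisation.
#'
#' @param sample_id unique sample identifiers.
#' @param condition treatment condition labels.
#' @param assay `"IP"` or `"input"` per sample.
#' @param replicate biological replicate numbers (`>= 1`).
#' @param total_mapped_reads total mapped reads per library (`> 0`).
#' @return data.frame with the five columns above; (condition, assay,
#'   replicate) must be unique.
#' @export
sample_sheet <- function(sample_id, condition, assay, replicate,
                         total_mapped_reads) {
  x <- data.frame(sample_id = as.character(sample_id),
                  condition = as.character(condition),
                  assay = as.character(assay),
                  replicate = as.integer(replicate),
                  total_mapped_reads = as.numeric(total_mapped_reads),
                  stringsAsFactors = FALSE)
  if (anyDuplicated(x$sample_id)) stop("duplicate sample_id")
  if (!all(x$assay %in% c("IP", "input")))
    stop("assay must be 'IP' or 'input'")
  if (any(x$replicate < 1L)) stop("replicate must be >= 1")
  if (any(x$total_mapped_reads <= 0)) stop("total_mapped_reads must be > 0")
  if (anyDuplicated(x[c("condition", "assay", "replicate")]))
    stop("(condition, assay, replicate) must be unique")
  x
}

#' Count reads into restriction fragments by 5' position
#'
#' Each read is assigned to exactly one fragment: the fragment containing
#' its 5' start (interval coordinates are half-open, so a read starting
#' exactly on a boundary belongs to the downstream fragment).  Reads on
#' contigs absent from the fragment set are dropped with a warning; reads
#' whose 5' position falls outside the tiled region are dropped with a
#' message reporting the count.
#'
#' @param reads data.frame of read intervals with columns `contig`,
#'   `start` and optionally `end` and `strand`; the 5' position is `start`
#'   except for `-`-strand reads, where it is `end - 1`.
#' @param fragments data.frame as from [digest_to_fragments()]; sorted
#'   internally if needed.
#' @return integer vector of counts, one per fragment row (input order),
#'   named by fragment id.
#' @export
count_reads_to_fragments <- function(reads, fragments) {
  stopifnot(all(c("contig", "start") %in% names(reads)),
            all(c("contig", "start", "end", "id") %in% names(fragments)))
  pos <- reads$start
  if (!is.null(reads$strand) && !is.null(reads$end)) {
    neg <- !is.na(reads$strand) & reads$strand == "-"
    pos[neg] <- reads$end[neg] - 1L
  }
  counts <- stats::setNames(integer(nrow(fragments)), fragments$id)
  unknown <- !(reads$contig %in% fragments$contig)
  if (any(unknown)) {
    warning(sum(unknown), " read(s) on contig(s) absent from fragment set dropped")
    reads <- reads[!unknown, , drop = FALSE]
    pos <- pos[!unknown]
  }
  dropped <- 0L
  for (ctg in unique(fragments$contig)) {
    f <- fragments[fragments$contig == ctg, , drop = FALSE]
    ord <- order(f$start)
    f <- f[ord, , drop = FALSE]
    p <- pos[reads$contig == ctg]
    ok <- p >= f$start[1] & p < f$end[nrow(f)]
    dropped <- dropped + sum(!ok)
    idx <- findInterval(p[ok], f$start)
    tab <- tabulate(idx, nbins = nrow(f))
    counts[f$id] <- counts[f$id] + tab
  }
  if (dropped > 0L)
    message(dropped, " read(s) outside the tiled region dropped")
  counts
}

#' Remove low-coverage fragments
#'
#' Fragments with fewer than `min_count` reads are uninformative for the
#' enrichment test and are removed before testing.  Under the default
#' `rule = "any"` a fragment is removed when *any* sample falls below the
#' threshold (the strictest reading of "less than 10 counts per interval
#' in any sample"); `rule = "all"` removes it only when every sample does.
#' Row order is preserved and the operation is idempotent.
#'
#' @param counts integer matrix, fragments x samples, with fragment ids as
#'   rownames.
#' @param min_count minimum count threshold (default 10).
#' @param rule `"any"` (default) or `"all"`; see above.
#' @return the filtered count matrix (possibly with zero rows).
#' @export
filter_low_coverage <- function(counts, min_count = 10, rule = c("any", "all")) {
  rule <- match.arg(rule)
  stopifnot(is.matrix(counts), min_count >= 0)
  if (nrow(counts) == 0L) return(counts)
  below <- counts < min_count
  drop <- if (rule == "any") apply(below, 1L, any) else apply(below, 1L, all)
  counts[!drop, , drop = FALSE]
}

#' Size factors from total mapped reads
#'
#' Read counts are normalised to the total number of mapped reads of each
#' library, rescaled by the geometric mean of the totals so that factors
#' multiply to one: `factor_s = total_s / geometric_mean(totals)`.
#' Normalised counts are `count / factor`.
#'
#' By default the reference scale is the geometric mean of the totals of
#' the samples at hand; passing a fixed `reference_total` (for example
#' `1e6`, giving counts per million) makes the normalised counts of a
#' sample depend on that sample alone, so rescaling one library's counts
#' and total together leaves every downstream result untouched.
#'
#' @param totals numeric vector of total mapped reads (`> 0`), or a sample
#'   sheet from [sample_sheet()].
#' @param reference_total optional fixed denominator replacing the
#'   geometric mean.
#' @return numeric vector of size factors, named like the input.
#' @export
size_factors_total_mapped <- function(totals, reference_total = NULL) {
  if (is.data.frame(totals)) {
    t0 <- stats::setNames(totals$total_mapped_reads, totals$sample_id)
  } else t0 <- totals
  if (any(t0 <= 0)) stop("total mapped reads must be > 0")
  ref <- if (is.null(reference_total)) exp(mean(log(t0))) else reference_total
  t0 / ref
}

#' Normalise a count matrix by size factors
#'
#' @param counts fragments x samples count matrix.
#' @param size_factors per-sample factors from [size_factors_total_mapped()].
#' @return matrix of normalised counts `count / factor`.
#' @export
normalize_counts <- function(counts, size_factors) {
  stopifnot(ncol(counts) == length(size_factors))
  sweep(counts, 2L, size_factors, "/")
}

#' Method-of-moments negative-binomial dispersion per fragment
#'
#' Counts are modelled as NB with variance `mu + alpha * mu^2`.  For each
#' fragment, the dispersion is estimated from normalised counts pooled
#' within groups by method of moments, `alpha_g = (var - mean) / mean^2`,
#' and the per-fragment estimate is the maximum over groups, floored at
#' `alpha_min` (the Poisson limit).  All-zero fragments get `alpha_min`.
#'
#' @param counts fragments x samples count matrix.
#' @param group group label per sample (two or more samples in at least
#'   one group).
#' @param size_factors optional per-sample size factors (default all 1).
#' @param alpha_min dispersion floor (default `1e-8`).
#' @return numeric vector of dispersions, one per fragment.
#' @export
estimate_dispersion <- function(counts, group, size_factors = NULL,
                                alpha_min = 1e-8) {
  stopifnot(is.matrix(counts), length(group) == ncol(counts))
  if (is.null(size_factors)) size_factors <- rep(1, ncol(counts))
  q <- normalize_counts(counts, size_factors)
  groups <- unique(group)
  sizes <- vapply(groups, function(g) sum(group == g), integer(1))
  if (!any(sizes >= 2L))
    stop("at least one group needs >= 2 samples to estimate dispersion")
  alpha <- rep(alpha_min, nrow(counts))
  for (g in groups[sizes >= 2L]) {
    qg <- q[, group == g, drop = FALSE]
    m <- rowMeans(qg)
    v <- apply(qg, 1L, var)
    a <- ifelse(m > 0, (v - m) / m^2, alpha_min)
    alpha <- pmax(alpha, a, na.rm = TRUE)
  }
  unname(alpha)
}

#' Negative-binomial Wald test for two-group enrichment
#'
#' The core enrichment/differential test of the pipeline.  For each
#' fragment the two group means are fitted on the normalised-count scale;
#' the effect is `log2fc = log2((mu_trt + c) / (mu_ref + c))` with
#' pseudo-mean `c` guarding against zero group means.  The standard error
#' comes from the delta method using the NB variance `mu + alpha*mu^2`
#' applied on the normalised-count scale, so the group-mean variance is
#' `(mu_g + alpha*mu_g^2) / n_g`; the p-value is two-sided from the Wald
#' statistic against the standard normal.  P-values are
#' Benjamini-Hochberg adjusted ([bh_adjust()]).  Because the statistic
#' depends on the data only through the normalised counts, rescaling one
#' library's counts together with its size factor leaves every result
#' unchanged.
#'
#' @param counts fragments x samples count matrix with fragment ids as
#'   rownames; filter low-coverage fragments first
#'   ([filter_low_coverage()]).
#' @param group group label per sample; exactly two distinct labels.
#' @param reference the label of the reference (denominator) group.
#' @param size_factors optional per-sample size factors (default all 1).
#' @param dispersion optional per-fragment dispersions; estimated with
#'   [estimate_dispersion()] when `NULL`.  Negative values are floored at
#'   zero.
#' @param pseudo_mean pseudo-mean `c` (default 0.5).
#' @return data.frame with columns `fragment`, `baseMean`, `log2fc`, `se`,
#'   `pvalue`, `padj`.
#' @export
nb_wald_test <- function(counts, group, reference, size_factors = NULL,
                         dispersion = NULL, pseudo_mean = 0.5) {
  stopifnot(is.matrix(counts), length(group) == ncol(counts))
  levels <- unique(group)
  if (length(levels) != 2L || !reference %in% levels)
    stop("group must have exactly two levels including the reference")
  treatment <- setdiff(levels, reference)
  if (is.null(size_factors)) size_factors <- rep(1, ncol(counts))
  if (is.null(dispersion))
    dispersion <- estimate_dispersion(counts, group, size_factors)
  alpha <- pmax(dispersion, 0)
  q <- normalize_counts(counts, size_factors)
  ref <- group == reference
  trt <- group == treatment
  m_r <- rowMeans(q[, ref, drop = FALSE])
  m_t <- rowMeans(q[, trt, drop = FALSE])
  lfc <- log2((m_t + pseudo_mean) / (m_r + pseudo_mean))
  # Var(mean_g) = (mu_g + alpha mu_g^2) / n_g
  vm_r <- (m_r + alpha * m_r^2) / sum(ref)
  vm_t <- (m_t + alpha * m_t^2) / sum(trt)
  se <- sqrt(vm_r / (m_r + pseudo_mean)^2 + vm_t / (m_t + pseudo_mean)^2) / log(2)
  z <- ifelse(se == 0, 0, lfc / se)
  p <- 2 * pnorm(-abs(z))
  data.frame(fragment = if (is.null(rownames(counts)))
               as.character(seq_len(nrow(counts))) else rownames(counts),
             baseMean = rowMeans(q), log2fc = lfc, se = se,
             pvalue = p, padj = bh_adjust(p),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up BH with monotonicity enforcement, capped at 1 (via
#' [stats::p.adjust()]).  `NA`/`NaN` inputs are propagated unchanged and
#' excluded from the ranking.
#'
#' @param p numeric vector of p-values in `[0, 1]` (plus `NA`/`NaN`).
#' @return adjusted p-values.
#' @export
bh_adjust <- function(p) {
  ok <- is.finite(p)
  if (any(p[ok] < 0 | p[ok] > 1)) stop("p-values must lie in [0, 1]")
  out <- p
  out[ok] <- p.adjust(p[ok], method = "BH")
  out
}

#' Reads per kilobase per million mapped reads
#'
#' `rpkm = count / (length_kb * total / 1e6)`.
#'
#' @param counts fragments x samples count matrix.
#' @param lengths fragment lengths in bp (`> 0`), one per row.
#' @param totals total mapped reads per sample, one per column.
#' @return matrix of RPKM values with the same dimensions as `counts`.
#' @export
rpkm <- function(counts, lengths, totals) {
  stopifnot(length(lengths) == nrow(counts), length(totals) == ncol(counts),
            all(lengths > 0), all(totals > 0))
  sweep(counts / (lengths / 1000), 2L, totals / 1e6, "/")
}
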