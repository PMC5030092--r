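#' Studentise a covariate
#'
#' Centres and scales to mean 0 and sample (n-1) standard deviation 1,
#' the standardisation applied to matching covariates before Euclidean
#' distances are computed.  A zero-variance input maps to all zeros, with
#' a warning.
#'
#' @param x numeric vector with at least two values.
#' @return standardised vector.
#' @export
studentize <- function(x) {
  stopifnot(length(x) >= 2L, !anyNA(x))
  s <- sd(x)
  if (s == 0) {
    warning("zero-variance covariate studentised to all zeros")
    return(rep(0, length(x)))
  }
  (x - mean(x)) / s
}

#' Greedy nearest-neighbour covariate matching without replacement
#'
#' Builds a control gene set matched to a test set on covariates
#' (by default replication timing and mean expression).  Covariates are
#' studentised jointly over the test and candidate genes; test genes are
#' visited in input order and each is matched to the unused candidate at
#' minimal Euclidean distance, ties broken lexicographically by gene id.
#' The result has exactly one control per test gene and no control is
#' reused.  The input-order dependence is deliberate and documented; a
#' caller wanting an order-free variant can pre-shuffle the test set under
#' its own seed.
#'
#' @param test character vector of test gene ids.
#' @param candidates character vector of candidate gene ids (disjoint from
#'   `test`, at least as many as `test`).
#' @param covariates numeric matrix or data.frame of covariates with gene
#'   ids as rownames, covering all test and candidate genes.
#' @return data.frame with `test_gene`, `matched_gene`, `distance`
#'   (studentised Euclidean).
#' @export
greedy_match <- function(test, candidates, covariates) {
  stopifnot(length(candidates) >= length(test),
            !any(test %in% candidates))
  all_ids <- c(test, candidates)
  if (!all(all_ids %in% rownames(covariates)))
    stop("covariates missing for some genes")
  X <- as.matrix(covariates[all_ids, , drop = FALSE])
  X <- apply(X, 2L, studentize)
  xt <- X[seq_along(test), , drop = FALSE]
  xc <- X[length(test) + seq_along(candidates), , drop = FALSE]
  d2 <- matrix(0, length(test), length(candidates),
               dimnames = list(test, candidates))
  for (k in seq_len(ncol(X)))
    d2 <- d2 + outer(xt[, k], xc[, k], "-")^2
  used <- logical(length(candidates))
  matched <- character(length(test))
  dist_out <- numeric(length(test))
  for (i in seq_along(test)) {
    d <- d2[i, ]
    d[used] <- Inf
    if (all(is.infinite(d))) stop("candidates exhausted")
    best <- which(d == min(d))
    j <- best[order(candidates[best])[1L]]
    matched[i] <- candidates[j]
    dist_out[i] <- sqrt(d[j])
    used[j] <- TRUE
  }
  data.frame(test_gene = test, matched_gene = matched, distance = dist_out,
             stringsAsFactors = FALSE)
}

#' Two-tailed bootstrap-of-medians test
#'
#' Tests whether the medians of a test set and its matched control set
#' differ.  The observed statistic is
#' `delta = median(test) - median(matched)`.  Both sets are pooled; each
#' resample draws a pseudo-test set of size `|test|` and a pseudo-matched
#' set of size `|matched|` from the pool (with replacement under the
#' default `scheme = "bootstrap"`; without replacement, a permutation
#' null, under `scheme = "permutation"`) and the p-value is the fraction
#' of resamples whose absolute median difference reaches `|delta|`,
#' floored at `1 / n_resamples` so it is never exactly zero.
#' Deterministic given `seed`.
#'
#' @param test,matched numeric value vectors (non-empty, no `NA`; drop
#'   sentinel values first).
#' @param n_resamples number of resamples (default 10000; the full-scale
#'   published analysis used 1e6).
#' @param seed optional integer seed; when `NULL` the current RNG stream
#'   is used.
#' @param scheme `"bootstrap"` (pooled, with replacement; default) or
#'   `"permutation"` (pooled, without replacement).
#' @param mutation_class optional label carried into the result.
#' @return object of class `drip_enrichment`: a list with
#'   `mutation_class`, `median_test`, `median_matched`, `delta_median`,
#'   `n_test`, `n_matched`, `n_resamples`, `pvalue`, `scheme`, `seed`.
#' @examples
#' bootstrap_median_test(rnorm(20), rnorm(20), n_resamples = 1000, seed = 1)
#' @export
bootstrap_median_test <- function(test, matched, n_resamples = 10000L,
                                  seed = NULL,
                                  scheme = c("bootstrap", "permutation"),
                                  mutation_class = NA_character_) {
  scheme <- match.arg(scheme)
  stopifnot(length(test) >= 1L, length(matched) >= 1L,
            !anyNA(test), !anyNA(matched))
  if (n_resamples < 1) stop("n_resamples must be >= 1")
  delta <- median(test) - median(matched)
  # sorted pool: the resampling null depends on the pooled values only,
  # so exchanging equal-sized test and matched sets leaves p unchanged
  pool <- sort(c(test, matched))
  run <- function() boot_median_count(pool, length(test), length(matched),
                                      n_resamples, abs(delta),
                                      scheme == "permutation")
  count <- if (is.null(seed)) run() else withr::with_seed(as.integer(seed), run())
  structure(list(mutation_class = mutation_class,
                 median_test = median(test),
                 median_matched = median(matched),
                 delta_median = delta,
                 n_test = length(test), n_matched = length(matched),
                 n_resamples = n_resamples,
                 pvalue = max(count / n_resamples, 1 / n_resamples),
                 scheme = scheme, seed = seed),
            class = "drip_enrichment")
}

#' @export
print.drip_enrichment <- function(x, ...) {
  cat("Two-tailed bootstrap of medians",
      if (!is.na(x$mutation_class)) sprintf("(%s)", x$mutation_class), "\n")
  cat(sprintf("  test set:    n = %d, median = %.4g\n", x$n_test, x$median_test))
  cat(sprintf("  matched set: n = %d, median = %.4g\n", x$n_matched,
              x$median_matched))
  cat(sprintf("  difference of medians: %.4g\n", x$delta_median))
  cat(sprintf("  p-value: %.3g (%s resampling, %s resamples%s)\n", x$pvalue,
              x$scheme, format(x$n_resamples, big.mark = ","),
              if (is.null(x$seed)) "" else sprintf(", seed %d", x$seed)))
  invisible(x)
}

#' Simple-somatic-mutation rate per kilobase
#'
#' `rate = (count + pseudocount) / (length_bp / 1000)`, with its log10.
#' With the default zero pseudocount, a zero rate has no finite log: its
#' `log10_rate` is `NA`, a sentinel that callers exclude from medians.
#'
#' @param count mutation event count per gene (`>= 0`).
#' @param length_bp gene length in bp (`> 0`).
#' @param pseudocount added to the count before division (default 0).
#' @return data.frame with `rate` and `log10_rate`.
#' @export
mutation_rate_per_kb <- function(count, length_bp, pseudocount = 0) {
  stopifnot(all(length_bp > 0), all(count >= 0))
  rate <- (count + pseudocount) / (length_bp / 1000)
  data.frame(rate = rate,
             log10_rate = ifelse(rate > 0, log10(rate), NA_real_))
}

#' Mutation-enrichment test in E2-responsive genes
#'
#' The full matched-control analysis for one mutation class.  For
#' rearrangement classes (`structural_variant`, `translocation`) the test
#' set is the genes carrying at least one event (presence, not
#' recurrence), the candidates are all other genes, and the compared value
#' is the E2-induction z-score.  For `simple_somatic` the test set is the
#' induced genes (`z > z_threshold`), the candidates are the non-induced
#' genes, and the compared value is the log10 per-kilobase mutation rate
#' (zero-rate sentinels are excluded from both sets).  In both cases the
#' pipeline is studentise, greedy-match on the covariates, then the
#' two-tailed bootstrap of medians.
#'
#' @param genes gene table with columns `gene`, `z`, `length_bp` and the
#'   matching covariates (defaults `repli_timing`, `mean_expr`).
#' @param mutations data.frame with `gene`, `class`, `count` (one row per
#'   mutated gene and class; genes absent for a class have count 0).
#' @param mutation_class one of `"structural_variant"`, `"translocation"`,
#'   `"simple_somatic"`.
#' @param n_resamples,seed,scheme passed to [bootstrap_median_test()].
#' @param z_threshold induction cutoff for the simple-somatic split
#'   (default 2).
#' @param covariates names of the matching covariate columns.
#' @return a `drip_enrichment` object (see [bootstrap_median_test()]) with
#'   an additional `matching` element holding the matched pairs.
#' @export
run_enrichment <- function(genes, mutations,
                           mutation_class = c("structural_variant",
                                              "translocation",
                                              "simple_somatic"),
                           n_resamples = 10000L, seed = NULL,
                           scheme = c("bootstrap", "permutation"),
                           z_threshold = 2,
                           covariates = c("repli_timing", "mean_expr")) {
  mutation_class <- match.arg(mutation_class)
  scheme <- match.arg(scheme)
  stopifnot(all(c("gene", "z", "length_bp", covariates) %in% names(genes)),
            all(c("gene", "class", "count") %in% names(mutations)))
  mut <- mutations[mutations$class == mutation_class & mutations$count >= 1, ]
  unknown <- setdiff(mut$gene, genes$gene)
  if (length(unknown))
    stop("mutation gene(s) not in gene table: ",
         paste(utils::head(unknown, 5), collapse = ", "))
  cov <- as.matrix(genes[, covariates, drop = FALSE])
  rownames(cov) <- genes$gene
  if (mutation_class == "simple_somatic") {
    test_ids <- genes$gene[genes$z > z_threshold]
    cand_ids <- genes$gene[!(genes$z > z_threshold)]
    counts <- stats::setNames(rep(0, nrow(genes)), genes$gene)
    counts[mut$gene] <- mut$count
    vals <- mutation_rate_per_kb(counts[genes$gene], genes$length_bp)$log10_rate
    values <- stats::setNames(vals, genes$gene)
  } else {
    test_ids <- intersect(genes$gene, unique(mut$gene))
    cand_ids <- setdiff(genes$gene, test_ids)
    values <- stats::setNames(genes$z, genes$gene)
  }
  if (length(test_ids) == 0L) stop("empty test set for ", mutation_class)
  pairs <- greedy_match(test_ids, cand_ids, cov)
  v_test <- values[pairs$test_gene]
  v_matched <- values[pairs$matched_gene]
  n_na <- sum(is.na(v_test)) + sum(is.na(v_matched))
  if (n_na > 0L)
    message(n_na, " zero-rate sentinel value(s) excluded from the medians")
  res <- bootstrap_median_test(v_test[!is.na(v_test)],
                               v_matched[!is.na(v_matched)],
                               n_resamples = n_resamples, seed = seed,
                               scheme = scheme,
                               mutation_class = mutation_class)
  res$matching <- pairs
  res
}
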