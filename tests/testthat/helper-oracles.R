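# Independent oracles used to cross-check the implementation.  These are
# deliberately naive: plain sliding-window scans, exhaustive enumeration
# and direct numeric likelihood maximisation, sharing no code with the
# package internals they validate.

# all exact forward-strand occurrences of each recognition sequence by a
# brute-force window scan; returns cut positions (0-based)
naive_cut_positions <- function(seq, enzymes = drip_enzymes()) {
  L <- nchar(seq)
  cuts <- integer(0)
  for (i in seq_len(nrow(enzymes))) {
    rec <- enzymes$recognition[i]
    k <- nchar(rec)
    if (L < k) next
    starts <- seq_len(L - k + 1L)
    hit <- substring(seq, starts, starts + k - 1L) == rec
    cuts <- c(cuts, starts[hit] - 1L + enzymes$cut_offset[i])
  }
  sort(unique(cuts))
}

# fragment boundaries implied by a naive scan: unique cuts plus contig ends
naive_boundaries <- function(seq) {
  L <- nchar(seq)
  sort(unique(c(0L, naive_cut_positions(seq), L)))
}

# minimum total distance over all one-to-one assignments of test rows to
# candidate columns, by exhaustive recursion (instances <= 8)
optimal_assignment_sum <- function(d) {
  recurse <- function(i, used) {
    if (i > nrow(d)) return(0)
    best <- Inf
    for (j in seq_len(ncol(d))[!used]) {
      used[j] <- TRUE
      best <- min(best, d[i, j] + recurse(i + 1L, used))
      used[j] <- FALSE
    }
    best
  }
  recurse(1L, logical(ncol(d)))
}

# numeric NB likelihood-ratio test for a single fragment, two groups:
# free dispersion and group means under the alternative, common mean
# under the null
nb_lrt_pvalue <- function(x_ref, x_trt) {
  nll <- function(par, x1, x2, common) {
    mu1 <- exp(par[1])
    mu2 <- if (common) mu1 else exp(par[2])
    size <- exp(par[length(par)])
    -sum(dnbinom(x1, mu = mu1, size = size, log = TRUE)) -
      sum(dnbinom(x2, mu = mu2, size = size, log = TRUE))
  }
  m <- mean(c(x_ref, x_trt))
  fit0 <- optim(c(log(m + 0.5), 2), nll, x1 = x_ref, x2 = x_trt,
                common = TRUE, method = "Nelder-Mead")
  fit1 <- optim(c(log(mean(x_ref) + 0.5), log(mean(x_trt) + 0.5), 2), nll,
                x1 = x_ref, x2 = x_trt, common = FALSE,
                method = "Nelder-Mead")
  stat <- max(2 * (fit0$value - fit1$value), 0)
  pchisq(stat, df = 1, lower.tail = FALSE)
}

# as above but with the dispersion held at a known value, so the
# comparison against the Wald route isolates the test statistic itself
nb_lrt_pvalue_fixed_alpha <- function(x_ref, x_trt, alpha) {
  size <- 1 / alpha
  nll <- function(par, x1, x2, common) {
    mu1 <- exp(par[1])
    mu2 <- if (common) mu1 else exp(par[2])
    -sum(dnbinom(x1, mu = mu1, size = size, log = TRUE)) -
      sum(dnbinom(x2, mu = mu2, size = size, log = TRUE))
  }
  fit0 <- optimize(function(p) nll(p, x_ref, x_trt, TRUE),
                   interval = log(c(0.01, 10 * mean(c(x_ref, x_trt)) + 10)))
  fit1a <- optimize(function(p) nll(p, x_ref, x_ref[0], TRUE),
                    interval = log(c(0.01, 10 * mean(x_ref) + 10)))
  fit1b <- optimize(function(p) nll(p, x_trt, x_trt[0], TRUE),
                    interval = log(c(0.01, 10 * mean(x_trt) + 10)))
  stat <- max(2 * (fit0$objective - fit1a$objective - fit1b$objective), 0)
  pchisq(stat, df = 1, lower.tail = FALSE)
}

random_dna <- function(n, alphabet = c("A", "C", "G", "T")) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

revcomp <- function(seq) {
  chartr("ACGTN", "TGCAN", paste(rev(strsplit(seq, "")[[1]]), collapse = ""))
}
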