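---
title: "Methods: fragment-centric DRIP-seq analysis and matched-control mutation enrichment"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: fragment-centric DRIP-seq analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dripseq)
```

This vignette is the package's account of its own methods: the models and
procedures, the tunable parameters and why their defaults are what they
are, what the synthetic-data generator does and does not emulate, and the
numerical and design decisions a maintainer would want written down.
Nothing here states an empirical result that the test suite or
`scripts/acceptance.R` does not itself compute.

## 1. Restriction fragments as count units

DRIP preserves the fragile RNA-DNA hybrid by digesting the genome with a
five-enzyme cocktail instead of sonicating it, so every library is
quantified over the same fixed intervals: the fragments between cut
sites. `find_restriction_sites()` reports every exact forward-strand
match of each recognition sequence — all five cocktail sequences are
palindromic, so a forward scan is complete — and `digest_to_fragments()`
places boundaries at the *cut positions* (recognition start + canonical
offset: BsrGI `T^GTACA`, EcoRI `G^AATTC`, HindIII `A^AGCTT`, SspI
`AAT^ATT`, XbaI `T^CTAGA`). The cut-position convention matches the
physical chemistry; because the original interval files could equally
have been built from recognition starts, `boundary =
"recognition_start"` is available and the default is documented rather
than asserted. Single cut coordinates are used: the few-base stagger
between strand nicks is far below fragment resolution.

Conventions worth stating once:

* all coordinates are 0-based half-open (BED);
* matching requires exact base equality, so recognition sites spanning an
  `N` are not reported; ambiguity codes other than `N` are rejected
  rather than guessed at;
* duplicate cut positions collapse to one boundary, so fragments always
  tile `[0, contig_length)` exactly — a property asserted against random
  genomes, with a naive sliding-window scan as the independent oracle.

GC skew, `(G−C)/(G+C)` per window, is computed from sequence
(`gc_skew_profile()`); windows without any G or C take the value 0 by
convention, and `N` counts as neither.

## 2. The count model

### Normalisation

Counts are normalised to each library's total mapped reads.
`size_factors_total_mapped()` rescales totals by their geometric mean so
factors multiply to one, which keeps normalised counts on the scale of
the observed counts. The geometric-mean reference does mean that one
sample's factor depends on the other samples' totals; passing a fixed
`reference_total` (counts-per-million style) makes each sample's
normalisation self-contained, and in that mode rescaling one library's
counts together with its total provably leaves every downstream result
unchanged (the test statistic depends on the data only through normalised
counts). Median-of-ratios normalisation is deliberately *not* used: the
stated normalisation of the original analysis is total mapped reads.

### Filtering

`filter_low_coverage()` removes a fragment when **any** sample has fewer
than `min_count = 10` reads — the strictest reading of "fewer than 10 in
any sample" — with `rule = "all"` as the lenient alternative. The filter
is idempotent and order-preserving.

### Enrichment and differential testing

For two groups the per-fragment test (`nb_wald_test()`) fits the group
means on the normalised scale and forms

\[
\log_2\!\mathrm{FC} = \log_2\frac{\hat\mu_t + c}{\hat\mu_r + c},
\qquad
\mathrm{se} = \frac{1}{\ln 2}\sqrt{
  \frac{\hat\mu_r + \alpha\hat\mu_r^2}{n_r(\hat\mu_r + c)^2} +
  \frac{\hat\mu_t + \alpha\hat\mu_t^2}{n_t(\hat\mu_t + c)^2}},
\]

a delta-method standard error from the NB variance \(\mu + \alpha\mu^2\),
with the two-sided p-value from the standard normal. The pseudo-mean
\(c = 0.5\) guards the fold change when a group mean is zero (an all-zero
fragment yields `log2fc = 0`, `p = 1`, never `NaN`). Dispersion
(`estimate_dispersion()`) is method-of-moments within groups,
\(\hat\alpha_g = (\widehat{\mathrm{var}} - \bar q)/\bar q^2\), taking the
maximum over groups and flooring at \(10^{-8}\) (the Poisson limit). The
maximum is intentionally conservative: with three replicates a per-group
moment estimate is noisy, and underestimating \(\alpha\) inflates false
positives much more than overestimating it deflates power.

A full iteratively-reweighted GLM fit would add nothing for a two-group
design without covariates; the Wald route is cross-checked in the test
suite against a numeric likelihood-ratio oracle (same fixed dispersion,
eight replicates per group — at three replicates with free dispersion the
two statistics genuinely differ by up to ~0.2 in p, which is a property
of small-sample NB inference, not a defect of either route).

**Calibration honestly stated.** With three replicates per group the
plug-in Wald p-values are mildly anti-conservative near zero (roughly 8%
below 0.05 under the null instead of 5%; Kolmogorov–Smirnov distance from
uniform around 0.04 at 5,000 fragments). Consequently BH at 0.1 calls a
small number of null fragments (~0.5–1% even with the consistency rule)
rather than exactly zero, and the empirical FDR of peak lists sits near
the nominal level rather than strictly below it. The acceptance suite
pins these magnitudes.

### Peak and differential calls

A *DRIP peak* is a fragment with positive fold change (IP over input) and
`padj < alpha`; `alpha = 0.1` mirrors the stated differential threshold,
since no separate peak-calling threshold was published. Calling is
monotone in `alpha`. Differential calling between conditions runs on the
union of DRIP-positive fragments and a background of "similarly-sized"
negative intervals; since no mechanism for "similarly-sized" was
published, `select_negative_intervals()` stratifies candidates over the
length deciles of the positive set (borrowing from the nearest stratum,
with a warning, when one runs dry). The per-replicate requirement is
implemented as *sign consistency* of each replicate pair's fold change,
not per-replicate significance: a single replicate pair has no dispersion
estimate of its own, so per-pair significance would be arbitrary. Both
interpretations are supported (`require_replicate_consistency`), and the
consistency rule can only remove calls, never add them.

### Gene assignment and profiles

`assign_to_genes()` measures distance to the *gene body* (not the TSS),
assigns within 1 kb, and breaks ties by smaller distance then
lexicographic gene id, making outputs order-independent.
`metagene_profile()` averages per-base coverage over a fixed 5' flank,
a length-rescaled body, and a 3' flank, reversing minus-strand genes;
flanks beyond the covered range contribute zeros.

## 3. E2-responsiveness and the GRO-seq cross-table

`e2_zscore()` is the exact closed form
\((\mu_{E2}-\mu_{mock})/\sqrt{\sigma^2_{E2}+\sigma^2_{mock}}\) with no
small-sample correction and no log transform (expression units are
treated as opaque; none was published). Degenerate inputs are explicit:
both standard deviations zero gives 0 for equal means and a signed
infinity *sentinel* (with a warning) otherwise. The induced class is
strictly `z > 2`; a gene at exactly 2 is non-induced.

The DRIP-by-GRO-seq quadrant labels require both `padj_drip <
alpha_drip` (default 0.1) and `padj_gro < alpha_gro`. The source analysis
states the GRO-seq cutoff as 0.5 in one place and 0.9 in another;
rather than silently pick one, `alpha_gro` has **no default** and both
published values ship as named presets (`groseq_alpha_presets()`). The
four sign-pair labels partition the significant regions; everything else
is `unclassified`.

## 4. Matched controls and the bootstrap of medians

Mutation burden correlates with replication timing and expression, so a
raw comparison of mutated versus non-mutated genes would confound
E2-responsiveness with those covariates. `greedy_match()` studentises
the covariates jointly over test and candidate genes and walks the test
set in input order, giving each gene the nearest unused candidate by
Euclidean distance (ties broken lexicographically, so results are
reproducible). Greedy matching is order-dependent by construction; the
order dependence is documented, a caller can pre-shuffle under a seed,
and the test suite checks the greedy total distance against a brute-force
optimal assignment on small instances (greedy is never better, and the
match still removes most of the covariate imbalance relative to a random
control subset).

`bootstrap_median_test()` implements the two-tailed bootstrap of medians:
pool both sets, resample pseudo-sets of the original sizes with
replacement, and count resamples whose \(|\Delta^*|\) reaches the
observed \(|\Delta|\); `scheme = "permutation"` (without replacement) is
the config alternative, since the published description ("re-sampled into
sets with the same size as the test and matched sets") does not pin the
scheme down. The p-value is floored at `1/n_resamples` and never zero.
The pooled values are sorted before resampling, which makes the p-value
exactly invariant to exchanging equal-sized test and matched sets.
Resample counting uses `>=`, so two identical sets give exactly `p = 1`.
Defaults use 10,000 resamples — the p-value resolution floor of
\(10^{-4}\) is ample for the planted effects exercised here — while the
full-fidelity 1,000,000 of the original analysis is one argument away.

Two behaviours of this statistic are worth knowing. First, for bimodal
data split half-and-half into two point masses the p-value *saturates*
near \(2\,P(\mathrm{Bin}(n,\tfrac12)\ge\lceil n/2\rceil+1)^2\) (≈ 0.34
at n = 20) no matter how far apart the masses are, because a pooled
pseudo-set lands its median on either mass with near-even odds; the unit
tests assert this closed form. Second, for unimodal data the pooled
median concentrates, and moderate shifts are detected with high power.
Real z-score and log-rate distributions are unimodal, so the statistic
behaves as intended there.

For the rearrangement classes (structural variants, translocations) the
compared value is the z-score and gene sets are presence-based ("at least
one event in any patient" — recurrence is not weighted). For simple
somatic mutations the comparison is between induced (`z > 2`) and matched
non-induced genes on `log10` per-kilobase rates
(`mutation_rate_per_kb()`); a zero rate with zero pseudocount has no
finite log and becomes an `NA` sentinel excluded from the medians.

## 5. What the synthetic data emulates

`simulation_config()` fixes the study conditions; one seed pins every
artifact byte-for-byte (each `simulate_*` step uses its own derived RNG
scope, so regenerating any one artifact is reproducible in isolation).

| parameter | default | why |
|---|---|---|
| genome | 2 × 50 kb, planted sites 0.25/kb/enzyme | a 6-mer occurs at random every ~4 kb; planting doubles site density so fragments have realistic few-hundred-bp to few-kb lengths at a size small enough for many simulation rounds |
| counts | NB, input mean 50, α = 0.05, 3 replicates | post-filter DRIP fragment counts are tens to hundreds; α = 0.05 is a typical biological-replicate dispersion; triplicates match the real design |
| planted effects | 10% enriched (log2fc 2), 5% induced (log2fc 2) | strong, unambiguous IP enrichment; induced fragments are a subset of enriched ones, as an induced R-loop is still a peak in E2 |
| library totals | log-normal, median 2 × 10⁶, sdlog 0.15 | realistic spread so size factors are exercised, not degenerate |
| genes | 3,000; 25% induced; z-margin 1 | a panel the size of an expressed-gene subset; E2 regulates a sizeable fraction of the expressed transcriptome, and planted induced genes sit at z ≥ 3 so the z > 2 classifier should (and does) recover them essentially exactly |
| covariates | cor(log expr, timing) = 0.6 | expressed genes replicate early; 0.6 gives matching something real to correct |
| mutations | SV 0.3 / translocation 0.2 baseline, odds 3 for induced; SSM 2/kb, ×⅓ in induced | across hundreds of whole genomes a large minority of genes carries ≥1 rearrangement; odds 3 is the planted-enrichment condition, and the simple-somatic depletion mirrors the reported direction |

These values were chosen once, at design time, as the package's reference
conditions and are not tuned per test. Gene lengths are log-normal with
median 10 kb so per-kilobase rates vary realistically.

What the generator does **not** emulate — and hence what passing tests do
not show: non-uniform base composition and real restriction-site
clustering, GC/mappability bias in counts, dispersion that varies with
mean, correlated fragments along the genome, patient-level mutation
recurrence, and any coupling between a gene's *covariates* and its
mutation odds beyond the planted induced-status effect. On real data the
matched-control construction has to work much harder; here it mainly
removes the expression shift that induction itself creates.

## 6. Problem sizes and numerical choices

The validation suite runs at desk scale by design: the digest oracle uses
1,000 random 10-kb sequences; NB calibration uses 5,000 null and 2,000
planted fragments at 3 vs 3; bootstrap calibration uses 500 repetitions
of 2,000 resamples; the end-to-end planted-enrichment study runs 100
simulations (plus 100 under the null) on a 40-kb genome with 10,000
resamples each. The bootstrap inner loop (resample + two medians) is
compiled (Rcpp) and draws from R's RNG, so it is seed-reproducible and
fast enough that resample counts, not implementation, set the runtime.

Remaining numerical conventions: BH adjustment propagates `NaN` inputs
unchanged and excludes them from ranking; Wald `se = 0` (possible only
when both group means are zero) yields `p = 1`; `estimate_dispersion()`
treats an all-zero fragment as Poisson; provenance headers on every
output file carry version, parameters and seed but never a timestamp, so
identical runs are byte-identical.
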