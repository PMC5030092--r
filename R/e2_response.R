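#' Estrogen-induction z-score from expression summaries
#'
#' Quantifies how strongly a gene responds to estrogen (E2) given the mean
#' and standard deviation of its expression under mock and E2 treatment:
#' `z = (mu_E2 - mu_mock) / sqrt(sd_E2^2 + sd_mock^2)`.  No small-sample
#' correction is applied and expression units are treated as opaque.
#' When both standard deviations are zero the score is 0 for equal means
#' and a signed infinity (a flagged sentinel, with a warning) otherwise.
#'
#' @param mu_mock,sd_mock mean and standard deviation under mock
#'   treatment.
#' @param mu_e2,sd_e2 mean and standard deviation under E2 treatment.
#' @return numeric vector of z-scores.
#' @examples
#' e2_zscore(1, 1, 3, 1)   # 2 / sqrt(2)
#' @export
e2_zscore <- function(mu_mock, sd_mock, mu_e2, sd_e2) {
  stopifnot(all(sd_mock >= 0, na.rm = TRUE), all(sd_e2 >= 0, na.rm = TRUE))
  denom <- sqrt(sd_e2^2 + sd_mock^2)
  num <- mu_e2 - mu_mock
  z <- num / denom
  degenerate <- denom == 0
  z[degenerate & num == 0] <- 0
  if (any(degenerate & num != 0, na.rm = TRUE)) {
    warning("zero variance with unequal means: z-score is a signed-infinity sentinel")
    z[degenerate & num != 0] <- sign(num[degenerate & num != 0]) * Inf
  }
  z
}

#' Classify genes as E2-induced by z-score
#'
#' A gene is `"induced"` iff its z-score strictly exceeds the threshold
#' (`z > 2` by default); a gene exactly at the threshold is
#' `"non_induced"`.
#'
#' @param z numeric vector of z-scores from [e2_zscore()].
#' @param threshold induction threshold (default 2).
#' @return character vector, `"induced"` or `"non_induced"` (`NA` for
#'   `NA` input).
#' @export
classify_induced <- function(z, threshold = 2) {
  ifelse(is.na(z), NA_character_,
         ifelse(z > threshold, "induced", "non_induced"))
}

#' Published significance presets for the GRO-seq arm
#'
#' The DRIP-by-GRO-seq categorisation was described with two different
#' GRO-seq adjusted-p cutoffs: 0.5 in the methods prose and 0.9 in the
#' enumerated figure criteria.  Neither is treated as a default;
#' [categorize_drip_groseq()] requires `alpha_gro` explicitly and both
#' published values are available here as named presets.
#'
#' @return named numeric vector with elements `methods_prose` (0.5) and
#'   `figure_criteria` (0.9).
#' @export
groseq_alpha_presets <- function() {
  c(methods_prose = 0.5, figure_criteria = 0.9)
}

#' Categorise regions by DRIP and GRO-seq fold-change quadrant
#'
#' Cross-tabulates estrogen-induced changes in R-loop signal (DRIP) with
#' changes in nascent transcription (GRO-seq) over a common region set.
#' A region is labelled only when both tests are significant
#' (`padj_drip < alpha_drip` and `padj_gro < alpha_gro`); the label is the
#' sign pair of the two log2 fold changes, otherwise `"unclassified"`.
#'
#' @param drip,gro data.frames from [nb_wald_test()] keyed on the same
#'   `fragment` ids.
#' @param alpha_drip DRIP adjusted-p threshold (default 0.1).
#' @param alpha_gro GRO-seq adjusted-p threshold; no default — pass one of
#'   [groseq_alpha_presets()] or an explicit value.
#' @return data.frame with `fragment`, `log2fc_drip`, `log2fc_gro`,
#'   `quadrant` (one of `up_drip_up_gro`, `up_drip_down_gro`,
#'   `down_drip_up_gro`, `down_drip_down_gro`, `unclassified`).
#' @export
categorize_drip_groseq <- function(drip, gro, alpha_drip = 0.1, alpha_gro) {
  if (missing(alpha_gro))
    stop("alpha_gro has no default; see groseq_alpha_presets()")
  stopifnot(alpha_drip > 0, alpha_drip <= 1, alpha_gro > 0, alpha_gro <= 1)
  m <- merge(drip[c("fragment", "log2fc", "padj")],
             gro[c("fragment", "log2fc", "padj")],
             by = "fragment", suffixes = c("_drip", "_gro"))
  sig <- !is.na(m$padj_drip) & m$padj_drip < alpha_drip &
    !is.na(m$padj_gro) & m$padj_gro < alpha_gro &
    m$log2fc_drip != 0 & m$log2fc_gro != 0
  quadrant <- rep("unclassified", nrow(m))
  quadrant[sig] <- paste0(ifelse(m$log2fc_drip[sig] > 0, "up", "down"), "_drip_",
                          ifelse(m$log2fc_gro[sig] > 0, "up", "down"), "_gro")
  data.frame(fragment = m$fragment, log2fc_drip = m$log2fc_drip,
             log2fc_gro = m$log2fc_gro, quadrant = quadrant,
             stringsAsFactors = FALSE)
}
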