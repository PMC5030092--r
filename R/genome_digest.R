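#' The DRIP restriction-enzyme cocktail
#'
#' DRIP-seq fragments the genome with a cocktail of five restriction
#' enzymes rather than by sonication, so that the fragile RNA-DNA hybrid
#' survives and the fragment boundaries are fixed, sequence-defined
#' intervals.  This returns the standard cocktail with canonical cut
#' offsets (`^` marks the cut): BsrGI `T^GTACA`, EcoRI `G^AATTC`, HindIII
#' `A^AGCTT`, SspI `AAT^ATT`, XbaI `T^CTAGA`.  All five recognition
#' sequences are palindromic, so a forward-strand search finds every site.
#'
#' @return data.frame with columns `name`, `recognition`, `cut_offset`.
#' @export
drip_enzymes <- function() {
  data.frame(name = c("BsrGI", "EcoRI", "HindIII", "SspI", "XbaI"),
             recognition = c("TGTACA", "GAATTC", "AAGCTT", "AATATT", "TCTAGA"),
             cut_offset = c(1L, 1L, 1L, 3L, 1L),
             stringsAsFactors = FALSE)
}

#' Construct and validate a restriction-enzyme specification
#'
#' @param name short identifier.
#' @param recognition recognition sequence over `{A,C,G,T}`.
#' @param cut_offset 0-based offset of the cut within the recognition
#'   sequence (a single coordinate per cut; nick offsets on the two
#'   strands are not modelled).
#' @return one-row data.frame with the same columns as [drip_enzymes()].
#' @export
enzyme_spec <- function(name, recognition, cut_offset) {
  recognition <- toupper(recognition)
  if (!nzchar(recognition) || grepl("[^ACGT]", recognition))
    stop("recognition sequence must be a non-empty string over {A,C,G,T}")
  cut_offset <- as.integer(cut_offset)
  if (is.na(cut_offset) || cut_offset < 0L || cut_offset > nchar(recognition))
    stop("cut_offset must lie within the recognition sequence")
  data.frame(name = as.character(name), recognition = recognition,
             cut_offset = cut_offset, stringsAsFactors = FALSE)
}

# Accepts a data.frame of enzyme specs or a character vector of names
# resolved against drip_enzymes(); unknown names are a configuration error.
resolve_enzymes <- function(enzymes) {
  if (is.character(enzymes)) {
    tab <- drip_enzymes()
    unknown <- setdiff(enzymes, tab$name)
    if (length(unknown))
      stop("unknown enzyme name(s): ", paste(unknown, collapse = ", "))
    enzymes <- tab[match(enzymes, tab$name), , drop = FALSE]
  }
  stopifnot(is.data.frame(enzymes),
            all(c("name", "recognition", "cut_offset") %in% names(enzymes)))
  do.call(rbind, Map(enzyme_spec, enzymes$name, enzymes$recognition,
                     enzymes$cut_offset))
}

normalize_genome <- function(genome) {
  if (inherits(genome, "DNAStringSet")) genome <- as.character(genome)
  stopifnot(is.character(genome))
  if (length(genome) && is.null(names(genome)))
    stop("genome sequences must be named by contig")
  genome <- toupper(genome)
  bad <- grepl("[^ACGTN]", genome)
  if (any(bad))
    stop("ambiguity codes other than N are not supported (contig ",
         paste(names(genome)[bad], collapse = ", "), ")")
  genome
}

#' Find restriction sites on a genome
#'
#' Reports every exact forward-strand match of each recognition sequence,
#' including overlapping matches.  Matching requires exact base equality,
#' so a site spanning an `N` is not reported.
#'
#' @param genome named character vector (or `DNAStringSet`) of contig
#'   sequences over `{A,C,G,T,N}`; case-insensitive.
#' @param enzymes enzyme table as from [drip_enzymes()] or a character
#'   vector of names from that table.
#' @return data.frame with columns `contig`, `position` (0-based start of
#'   the recognition match), `enzyme`, `cut_position`
#'   (`position + cut_offset`), sorted by (contig, position) with contigs
#'   in genome order.
#' @examples
#' find_restriction_sites(c(chr = "GGAATTCC"), "EcoRI")
#' @export
find_restriction_sites <- function(genome, enzymes = drip_enzymes()) {
  genome <- normalize_genome(genome)
  enzymes <- resolve_enzymes(enzymes)
  empty <- data.frame(contig = character(0), position = integer(0),
                      enzyme = character(0), cut_position = integer(0),
                      stringsAsFactors = FALSE)
  if (length(genome) == 0L) return(empty)
  res <- lapply(names(genome), function(ctg) {
    subject <- Biostrings::DNAString(genome[[ctg]])
    hits <- lapply(seq_len(nrow(enzymes)), function(i) {
      m <- Biostrings::matchPattern(enzymes$recognition[i], subject, fixed = TRUE)
      pos <- Biostrings::start(m) - 1L
      if (!length(pos)) return(NULL)
      data.frame(contig = ctg, position = pos, enzyme = enzymes$name[i],
                 cut_position = pos + enzymes$cut_offset[i],
                 stringsAsFactors = FALSE)
    })
    do.call(rbind, hits)
  })
  out <- do.call(rbind, c(list(empty), res))
  out <- out[order(match(out$contig, names(genome)), out$position,
                   out$enzyme, method = "radix"), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Digest contigs into restriction fragments
#'
#' Fragment boundaries are the sorted unique cut positions of the supplied
#' sites plus the contig ends, so the fragments of each contig are
#' disjoint, sorted, and tile `[0, contig_length)` exactly.  Duplicate cut
#' positions (two enzymes cutting at the same base) collapse to a single
#' boundary and zero-length fragments are never emitted.  By default the
#' boundary is the physical cut position; `boundary = "recognition_start"`
#' uses the start of the recognition match instead.
#'
#' @param contig_lengths named integer vector of contig lengths.
#' @param sites data.frame as from [find_restriction_sites()]; may be
#'   empty.
#' @param boundary `"cut"` (default) or `"recognition_start"`.
#' @return data.frame with columns `contig`, `start`, `end`, `id`
#'   (`"contig:start-end"`).
#' @examples
#' digest_to_fragments(c(chr = 100L),
#'   find_restriction_sites(c(chr = strrep("A", 100)), "EcoRI"))
#' @export
digest_to_fragments <- function(contig_lengths, sites,
                                boundary = c("cut", "recognition_start")) {
  boundary <- match.arg(boundary)
  stopifnot(!is.null(names(contig_lengths)), all(contig_lengths > 0))
  res <- lapply(names(contig_lengths), function(ctg) {
    L <- as.integer(contig_lengths[[ctg]])
    cuts <- integer(0)
    if (nrow(sites)) {
      s <- sites[sites$contig == ctg, , drop = FALSE]
      cuts <- if (boundary == "cut") s$cut_position else s$position
      if (length(cuts) && (min(cuts) < 0L || max(cuts) > L))
        stop("cut position out of bounds on contig ", ctg)
    }
    b <- sort(unique(c(0L, as.integer(cuts), L)))
    data.frame(contig = ctg, start = b[-length(b)], end = b[-1],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$id <- sprintf("%s:%d-%d", out$contig, out$start, out$end)
  rownames(out) <- NULL
  out
}

#' Digest a genome into DRIP count intervals
#'
#' Convenience wrapper running [find_restriction_sites()] and
#' [digest_to_fragments()].
#'
#' @inheritParams find_restriction_sites
#' @inheritParams digest_to_fragments
#' @return list with elements `sites` and `fragments`.
#' @export
digest_genome <- function(genome, enzymes = drip_enzymes(),
                          boundary = c("cut", "recognition_start")) {
  genome <- normalize_genome(genome)
  sites <- find_restriction_sites(genome, enzymes)
  frags <- digest_to_fragments(nchar(genome), sites, boundary = match.arg(boundary))
  list(sites = sites, fragments = frags)
}

#' GC-skew profile of a genome
#'
#' GC skew, `(G - C) / (G + C)` over a window, is the strand asymmetry in
#' guanine content that favours R-loop formation on the displaced strand.
#' One value is reported per window start; windows with no G or C (for
#' example all-`N` or AT-only windows) carry value 0.  `N` bases are not
#' counted as G or C.
#'
#' @param genome named character vector (or `DNAStringSet`) of contig
#'   sequences; a single unnamed sequence is also accepted.
#' @param window window size in bp (`>= 1`).
#' @param step step between window starts in bp (`>= 1`); defaults to
#'   `window` (non-overlapping windows).
#' @return data.frame with columns `contig`, `start`, `end`, `skew`
#'   (bedGraph-ready); values lie in `[-1, 1]`.
#' @examples
#' gc_skew_profile(c(chr = "GGGGCCCC"), window = 4)
#' @export
gc_skew_profile <- function(genome, window, step = window) {
  if (is.character(genome) && length(genome) == 1L && is.null(names(genome)))
    names(genome) <- "seq"
  genome <- normalize_genome(genome)
  stopifnot(window >= 1, step >= 1)
  window <- as.integer(window); step <- as.integer(step)
  res <- lapply(names(genome), function(ctg) {
    L <- nchar(genome[[ctg]])
    if (L < window)
      return(data.frame(contig = character(0), start = integer(0),
                        end = integer(0), skew = numeric(0)))
    freq <- Biostrings::letterFrequencyInSlidingView(
      Biostrings::DNAString(genome[[ctg]]), window, c("G", "C"))
    keep <- seq(1L, L - window + 1L, by = step)
    g <- freq[keep, "G"]; c0 <- freq[keep, "C"]
    denom <- g + c0
    skew <- ifelse(denom == 0, 0, (g - c0) / denom)
    data.frame(contig = ctg, start = keep - 1L, end = keep - 1L + window,
               skew = skew, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}
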