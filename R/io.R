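#' Provenance header lines for output files
#'
#' Every file the package writes starts with a comment block recording the
#' package version, the operation that produced it and the full parameter
#' set (including any seed), so a result file is self-describing.  The
#' block deliberately contains no timestamp: identical inputs must give
#' byte-identical outputs.
#'
#' @param command short name of the operation writing the file.
#' @param params named list of parameters to echo; `NULL` entries dropped.
#' @return character vector of `#`-prefixed lines.
#' @export
provenance_lines <- function(command, params = list()) {
  params <- params[!vapply(params, is.null, logical(1))]
  vals <- vapply(params, function(x) paste(format(x, trim = TRUE), collapse = ","),
                 character(1))
  c(sprintf("# dripseq %s | %s", as.character(packageVersion("dripseq")), command),
    if (length(vals)) sprintf("# %s=%s", names(vals), vals))
}

write_lines_then_table <- function(header, x, path, col.names) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  if (length(header)) writeLines(header, con)
  write.table(x, con, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = col.names)
  invisible(path)
}

#' Read a FASTA file into a named character vector
#'
#' Sequences are case-folded to upper case; record names are truncated at
#' the first whitespace.  Multi-contig files and CRLF line endings are
#' supported.
#'
#' @param path path to a FASTA file.
#' @return named character vector, one element per contig.
#' @export
read_fasta <- function(path) {
  seqs <- Biostrings::readDNAStringSet(path)
  if (length(seqs) == 0L) stop("no sequences in FASTA file: ", path)
  out <- toupper(as.character(seqs))
  names(out) <- sub("\\s.*$", "", names(seqs))
  out
}

#' Write sequences to a FASTA file
#'
#' @param seqs named character vector of sequences.
#' @param path output path.
#' @param width line width for wrapping.
#' @return the path, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 70L) {
  stopifnot(is.character(seqs), !is.null(names(seqs)))
  con <- file(path, open = "wt")
  on.exit(close(con))
  for (i in seq_along(seqs)) {
    writeLines(paste0(">", names(seqs)[i]), con)
    s <- seqs[[i]]
    starts <- seq(1L, max(nchar(s), 1L), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}

#' Read a BED3/BED6 interval file
#'
#' Coordinates are 0-based half-open.  1-based input is only converted when
#' explicitly requested via `one_based = TRUE`; it is never guessed.
#' Intervals are returned sorted by (contig, start, end) with a stable
#' tie-break.
#'
#' @param path path to a BED file; `#` comment lines are skipped.
#' @param one_based if `TRUE`, input starts are 1-based and are shifted
#'   down by one.
#' @return data.frame with columns `contig`, `start`, `end` and, when
#'   present in the file, `name`, `score`, `strand`.
#' @export
read_bed <- function(path, one_based = FALSE) {
  x <- read.table(path, sep = "\t", comment.char = "#", header = FALSE,
                  stringsAsFactors = FALSE, quote = "")
  if (ncol(x) < 3L) stop("BED file needs at least 3 columns: ", path)
  nm <- c("contig", "start", "end", "name", "score", "strand")
  names(x) <- nm[seq_len(min(ncol(x), 6L))]
  x <- x[seq_len(min(ncol(x), 6L))]
  if (one_based) x$start <- x$start - 1L
  x[order(x$contig, x$start, x$end, method = "radix"), , drop = FALSE]
}

#' Write intervals as BED
#'
#' Missing `name`/`score`/`strand` columns are filled with BED null values
#' (`"."`, `0`, `"."`).
#'
#' @param x data.frame with `contig`, `start`, `end` and optional
#'   `name`, `score`, `strand` columns.
#' @param path output path.
#' @param provenance optional header lines from [provenance_lines()].
#' @return the path, invisibly.
#' @export
write_bed <- function(x, path, provenance = NULL) {
  stopifnot(all(c("contig", "start", "end") %in% names(x)))
  out <- data.frame(contig = x$contig,
                    start = format(x$start, scientific = FALSE, trim = TRUE),
                    end = format(x$end, scientific = FALSE, trim = TRUE),
                    name = if ("name" %in% names(x)) x$name else ".",
                    score = if ("score" %in% names(x)) x$score else 0,
                    strand = if ("strand" %in% names(x)) x$strand else ".")
  write_lines_then_table(provenance, out, path, col.names = FALSE)
}

#' Read a bedGraph coverage file
#'
#' @param path path to a bedGraph file; `#` and `track` lines are skipped.
#' @return data.frame with columns `contig`, `start`, `end`, `value`,
#'   sorted by (contig, start).  Intervals within a contig must not
#'   overlap; regions not covered by any interval have implicit value 0.
#' @export
read_bedgraph <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^(#|track|browser)", lines) & nzchar(lines)]
  x <- read.table(text = lines, sep = "\t", header = FALSE,
                  stringsAsFactors = FALSE)
  if (ncol(x) != 4L) stop("bedGraph file needs 4 columns: ", path)
  names(x) <- c("contig", "start", "end", "value")
  x <- x[order(x$contig, x$start, x$end, method = "radix"), , drop = FALSE]
  same <- x$contig[-1] == x$contig[-nrow(x)]
  if (nrow(x) > 1L && any(same & x$start[-1] < x$end[-nrow(x)]))
    stop("overlapping intervals in bedGraph: ", path)
  rownames(x) <- NULL
  x
}

#' Write coverage as bedGraph
#'
#' @param x data.frame with `contig`, `start`, `end`, `value`.
#' @inheritParams write_bed
#' @return the path, invisibly.
#' @export
write_bedgraph <- function(x, path, provenance = NULL) {
  stopifnot(all(c("contig", "start", "end", "value") %in% names(x)))
  out <- data.frame(contig = x$contig,
                    start = format(x$start, scientific = FALSE, trim = TRUE),
                    end = format(x$end, scientific = FALSE, trim = TRUE),
                    value = format(x$value, trim = TRUE))
  write_lines_then_table(provenance, out, path, col.names = FALSE)
}

#' Read a tab-separated table with schema validation
#'
#' @param path path to a TSV file with a header row; `#` comment lines are
#'   skipped.
#' @param required character vector of column names that must be present;
#'   a missing column is an error naming the column.  Extra columns are
#'   preserved.
#' @return data.frame.
#' @export
read_tsv <- function(path, required = character(0)) {
  x <- read.table(path, sep = "\t", header = TRUE, comment.char = "#",
                  stringsAsFactors = FALSE, check.names = FALSE, quote = "")
  missing <- setdiff(required, names(x))
  if (length(missing))
    stop("missing required column(s): ", paste(missing, collapse = ", "),
         " in ", path)
  x
}

#' Write a data.frame as a tab-separated table
#'
#' @param x data.frame.
#' @inheritParams write_bed
#' @return the path, invisibly.
#' @export
write_tsv <- function(x, path, provenance = NULL) {
  write_lines_then_table(provenance, x, path, col.names = TRUE)
}
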