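#' Read and write FASTA/FASTQ files
#'
#' Sequence IO goes through Biostrings; these helpers convert to and from the
#' plain named-character representation used throughout the package.
#'
#' @param path file path.
#' @param x for `write_fasta`, a named character vector of sequences; for
#'   `write_fastq`, a data frame with columns `id`, `seq` and `qual`.
#' @return `read_fasta` returns a named character vector. `read_fastq` returns
#'   a data frame with columns `id`, `seq`, `qual`.
#' @export
read_fasta <- function(path) {
  s <- Biostrings::readDNAStringSet(path)
  setNames(as.character(s), names(s))
}

#' @rdname read_fasta
#' @export
write_fasta <- function(x, path) {
  s <- Biostrings::DNAStringSet(x)
  names(s) <- names(x)
  Biostrings::writeXStringSet(s, path)
  invisible(path)
}

#' @rdname read_fasta
#' @export
write_fastq <- function(x, path) {
  s <- Biostrings::DNAStringSet(x$seq)
  names(s) <- x$id
  q <- Biostrings::BStringSet(x$qual)
  Biostrings::writeXStringSet(s, path, format = "fastq", qualities = q)
  invisible(path)
}

#' @rdname read_fasta
#' @export
read_fastq <- function(path) {
  s <- Biostrings::readDNAStringSet(path, format = "fastq", with.qualities = TRUE)
  data.frame(id = names(s), seq = as.character(s),
             qual = as.character(S4Vectors::mcols(s)$qualities),
             stringsAsFactors = FALSE)
}

#' Read a multiple alignment (aligned FASTA or Stockholm)
#'
#' @param path file path.
#' @param format `"fasta"` or `"stockholm"`.
#' @return named character vector of aligned sequences (equal widths, gaps as
#'   `-`).
#' @export
read_alignment <- function(path, format = c("fasta", "stockholm")) {
  format <- match.arg(format)
  aln <- Biostrings::readDNAMultipleAlignment(path, format = format)
  m <- as.character(aln)
  setNames(as.character(m), rownames(aln))
}

#' Read and write BED interval files
#'
#' Minimal BED6 (contig, start, end, name, score, strand) with the package's
#' 0-based half-open coordinates, which BED shares.
#'
#' @param x data frame with columns `contig`, `start`, `end` and optionally
#'   `name`, `score`, `strand`.
#' @param path file path.
#' @return `read_bed` returns a data frame with the six BED columns.
#' @export
write_bed <- function(x, path) {
  out <- data.frame(
    contig = x$contig, start = x$start, end = x$end,
    name = if ("name" %in% names(x)) x$name else ".",
    score = if ("score" %in% names(x)) x$score else 0,
    strand = if ("strand" %in% names(x)) x$strand else "+")
  write.table(out, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_bed
#' @export
read_bed <- function(path) {
  x <- read.table(path, sep = "\t", header = FALSE, stringsAsFactors = FALSE)
  names(x) <- c("contig", "start", "end", "name", "score", "strand")[seq_len(ncol(x))]
  x
}

#' Read and write minimal SAM files
#'
#' Single-segment SAM records with `@HD`/`@SQ` header lines. `read_sam`
#' derives the aligned reference span from the CIGAR string (M/D/N/=/X
#' consume reference; soft clips do not), so externally produced SAM with
#' soft clips is ingested correctly.
#'
#' @param records alignment data frame as returned by
#'   [align_reads_minimal()] (columns `qname`, `flag`, `rname`, `pos`,
#'   `mapq`, `cigar`, `seq`).
#' @param ref_lengths named integer vector of reference lengths.
#' @param path file path.
#' @return `read_sam` returns a data frame with columns `qname`, `flag`,
#'   `rname`, `pos` (0-based), `mapq`, `cigar`, `seq`, `aligned_length`,
#'   `mapped`, `strand`, plus a `ref_lengths` attribute taken from `@SQ`.
#' @export
write_sam <- function(records, ref_lengths, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("@HD\tVN:1.6\tSO:unknown", con)
  writeLines(sprintf("@SQ\tSN:%s\tLN:%d", names(ref_lengths),
                     as.integer(ref_lengths)), con)
  writeLines(sprintf("%s\t%d\t%s\t%d\t%d\t%s\t*\t0\t0\t%s\t*",
                     records$qname, records$flag,
                     ifelse(records$mapped, records$rname, "*"),
                     ifelse(records$mapped, records$pos + 1L, 0L),
                     ifelse(records$mapped, records$mapq, 0L),
                     ifelse(records$mapped, records$cigar, "*"),
                     records$seq), con)
  invisible(path)
}

.cigar_ref_span <- function(cigar) {
  vapply(cigar, function(cg) {
    if (is.na(cg) || cg == "*") return(NA_integer_)
    ops <- gregexpr("\\d+[MIDNSHP=X]", cg)[[1]]
    toks <- regmatches(cg, gregexpr("\\d+[MIDNSHP=X]", cg))[[1]]
    n <- as.integer(sub("[A-Z=]$", "", toks))
    op <- sub("^\\d+", "", toks)
    sum(n[op %in% c("M", "D", "N", "=", "X")])
  }, integer(1), USE.NAMES = FALSE)
}

#' @rdname write_sam
#' @export
read_sam <- function(path) {
  lines <- readLines(path)
  hdr <- lines[startsWith(lines, "@")]
  body <- lines[!startsWith(lines, "@")]
  sq <- hdr[startsWith(hdr, "@SQ")]
  ref_lengths <- integer(0)
  if (length(sq)) {
    sn <- sub(".*\\bSN:([^\t]+).*", "\\1", sq)
    ln <- as.integer(sub(".*\\bLN:([0-9]+).*", "\\1", sq))
    ref_lengths <- setNames(ln, sn)
  }
  if (!length(body)) {
    out <- data.frame(qname = character(0))
    attr(out, "ref_lengths") <- ref_lengths
    return(out)
  }
  f <- strsplit(body, "\t", fixed = TRUE)
  get <- function(i) vapply(f, `[[`, character(1), i)
  flag <- as.integer(get(2))
  out <- data.frame(
    qname = get(1), flag = flag, rname = get(3),
    pos = as.integer(get(4)) - 1L, mapq = as.integer(get(5)),
    cigar = get(6), seq = get(10), stringsAsFactors = FALSE)
  out$mapped <- bitwAnd(flag, 4L) == 0L
  out$strand <- ifelse(bitwAnd(flag, 16L) == 16L, "-", "+")
  out$aligned_length <- .cigar_ref_span(out$cigar)
  attr(out, "ref_lengths") <- ref_lengths
  out
}

#' Read and write TSV matrices (samples x features)
#'
#' @param x numeric matrix with row and column names.
#' @param path file path.
#' @return `read_tsv_matrix` returns a numeric matrix.
#' @export
write_tsv_matrix <- function(x, path) {
  write.table(x, path, sep = "\t", quote = FALSE, col.names = NA)
  invisible(path)
}

#' @rdname write_tsv_matrix
#' @export
read_tsv_matrix <- function(path) {
  as.matrix(read.table(path, sep = "\t", header = TRUE, row.names = 1,
                       check.names = FALSE))
}
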