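# CN-MD: ITS copy number from shotgun reads, as the trimmed-mean ITS mapping
# depth divided by the median depth of single-copy marker genes. Includes a
# minimal internal aligner so the pipeline runs without an external mapper.

#' Minimal seed-and-extend read aligner
#'
#' Exact-seed lookup (three seed offsets per strand) followed by full-length
#' ungapped extension against both strands of every reference. A unique best
#' location gets MAPQ 42, tied best locations MAPQ 0, and reads without an
#' acceptable location are reported unmapped. This is a test-scale stand-in
#' for an external short-read mapper, not a general-purpose aligner.
#'
#' @param reads data frame with columns `id` and `seq` (e.g. from
#'   [simulate_shotgun_reads()]) or a named character vector.
#' @param references named character vector of reference sequences.
#' @param seed_length exact seed length in bp.
#' @param max_mismatch_frac maximum tolerated mismatch fraction of the read
#'   length for a location to be acceptable.
#' @return data frame of SAM-like records: `qname`, `flag`, `rname`, `pos`
#'   (0-based), `mapq`, `cigar`, `seq`, `aligned_length`, `mapped`,
#'   `strand`, `nmis`; attribute `ref_lengths`.
#' @export
align_reads_minimal <- function(reads, references, seed_length = 20,
                                max_mismatch_frac = 0.07) {
  if (is.character(reads))
    reads <- data.frame(id = if (is.null(names(reads)))
      paste0("read", seq_along(reads)) else names(reads),
      seq = unname(reads), stringsAsFactors = FALSE)
  if (!length(references)) stop("references must be non-empty")
  if (is.null(names(references)))
    names(references) <- paste0("ref", seq_along(references))
  res <- align_reads_cpp(reads$seq, unname(references), as.integer(seed_length),
                         max_mismatch_frac)
  rl <- nchar(reads$seq)
  mapped <- res$mapped
  out <- data.frame(
    qname = reads$id,
    flag = ifelse(!mapped, 4L, ifelse(res$strand == "-", 16L, 0L)),
    rname = ifelse(mapped, names(references)[res$ref], NA_character_),
    pos = res$pos, mapq = res$mapq,
    cigar = ifelse(mapped, paste0(rl, "M"), NA_character_),
    seq = reads$seq, aligned_length = ifelse(mapped, rl, NA_integer_),
    mapped = mapped, strand = res$strand, nmis = res$nmis,
    stringsAsFactors = FALSE)
  attr(out, "ref_lengths") <- setNames(nchar(references), names(references))
  out
}

#' Per-base depth from alignment records
#'
#' Records that are unmapped or below the MAPQ cutoff are excluded (the
#' pipeline filters mapping quality below 30); each surviving record
#' increments depth over `[pos, pos + aligned_length)`.
#'
#' @param records alignment data frame ([align_reads_minimal()] or
#'   [read_sam()]).
#' @param ref_lengths named integer vector; defaults to the records'
#'   `ref_lengths` attribute.
#' @param mapq_min minimum MAPQ kept (a record with MAPQ 29 contributes
#'   nothing at the default of 30; MAPQ 30 counts).
#' @return named list of integer depth vectors, one per reference.
#' @export
depth_from_alignments <- function(records, ref_lengths = NULL, mapq_min = 30) {
  if (is.null(ref_lengths)) ref_lengths <- attr(records, "ref_lengths")
  if (is.null(ref_lengths)) stop("ref_lengths not supplied or attached")
  keep <- records$mapped & records$mapq >= mapq_min
  r <- records[keep, , drop = FALSE]
  unknown <- setdiff(unique(r$rname), names(ref_lengths))
  if (length(unknown)) stop("records reference unknown sequences: ",
                            paste(unknown, collapse = ", "))
  out <- lapply(names(ref_lengths), function(rn) {
    L <- ref_lengths[[rn]]
    x <- r[r$rname == rn, , drop = FALSE]
    if (!nrow(x)) return(integer(L))
    ends <- x$pos + x$aligned_length
    if (any(ends > L)) {
      warning("record(s) extending past the end of ", rn, " clipped")
      ends <- pmin(ends, L)
    }
    starts <- pmin(x$pos, L - 1L) + 1L # 1-based start index
    inc <- tabulate(starts, nbins = L + 1L)
    dec <- tabulate(ends + 1L, nbins = L + 1L)
    cumsum(inc - dec)[seq_len(L)]
  })
  names(out) <- names(ref_lengths)
  out
}

#' End-trimmed mean depth of a gene
#'
#' Mean per-base depth after discarding the first and last `trim` bases,
#' whose depth is systematically deflated by read-edge effects. The mean is
#' itself the per-length normalisation (covered bases per usable base).
#'
#' @param depth integer/numeric per-base depth vector.
#' @param trim bases removed from each end (default 50).
#' @return list with `trimmed_mean_depth` and `usable_length`.
#' @export
trimmed_mean_depth <- function(depth, trim = 50) {
  L <- length(depth)
  if (L <= 2 * trim)
    stop("gene length ", L, " <= 2*trim; lower 'trim' for this gene")
  list(trimmed_mean_depth = mean(depth[(trim + 1):(L - trim)]),
       usable_length = L - 2L * trim)
}

#' Trimmed mean depths for every reference
#'
#' @param depth_table named list of depth vectors from
#'   [depth_from_alignments()].
#' @param trim bases trimmed from each end.
#' @return data frame with columns `ref`, `trimmed_mean_depth`,
#'   `usable_length`.
#' @export
gene_depths <- function(depth_table, trim = 50) {
  rows <- lapply(names(depth_table), function(rn) {
    g <- trimmed_mean_depth(depth_table[[rn]], trim)
    data.frame(ref = rn, trimmed_mean_depth = g$trimmed_mean_depth,
               usable_length = g$usable_length, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Estimate ITS copy number from mapping depths (CN-MD)
#'
#' The copy number is the ITS trimmed-mean depth divided by the median of the
#' single-copy marker-gene trimmed-mean depths; the median (not the mean)
#' guards against outlier marker genes with unusually high depth.
#'
#' @param its ITS depth: a number or a [trimmed_mean_depth()] result.
#' @param markers numeric vector of marker-gene trimmed-mean depths (or a
#'   [gene_depths()] data frame).
#' @param genome_id label stored in the result.
#' @return object of class `cn_md`: list with `genome`, `its_depth`,
#'   `marker_median_depth`, `cn_md`.
#' @export
estimate_cn_md <- function(its, markers, genome_id = "genome") {
  if (is.list(its) && !is.data.frame(its)) its <- its$trimmed_mean_depth
  if (is.data.frame(markers)) markers <- markers$trimmed_mean_depth
  if (!length(markers)) stop("at least one marker gene is required")
  md <- median(markers)
  if (md <= 0) stop("marker median depth is 0: copy number undefined")
  structure(list(genome = genome_id, its_depth = its,
                 marker_median_depth = md, cn_md = its / md),
            class = "cn_md")
}

#' @export
print.cn_md <- function(x, ...) {
  cat(sprintf("CN-MD for %s: ITS depth %.2f / marker median %.2f = %.2f\n",
              x$genome, x$its_depth, x$marker_median_depth, x$cn_md))
  invisible(x)
}

#' Run the full CN-MD pipeline on a read set
#'
#' Aligns reads to the ITS sequence plus the marker genes, filters by MAPQ,
#' computes end-trimmed mean depths and returns the depth-ratio copy number.
#'
#' @param reads read data frame (`id`, `seq`).
#' @param its_ref single named ITS reference sequence.
#' @param marker_refs named character vector of single-copy marker genes.
#' @param mapq_min MAPQ filter (default 30).
#' @param trim end trim in bp (default 50).
#' @param seed_length aligner seed length.
#' @param genome_id label for the result.
#' @return a `cn_md` object with an extra `gene_depths` element.
#' @export
cn_md_pipeline <- function(reads, its_ref, marker_refs, mapq_min = 30,
                           trim = 50, seed_length = 20, genome_id = "genome") {
  stopifnot(length(its_ref) == 1)
  refs <- c(its_ref, marker_refs)
  rec <- align_reads_minimal(reads, refs, seed_length = seed_length)
  dt <- depth_from_alignments(rec, mapq_min = mapq_min)
  gd <- gene_depths(dt, trim = trim)
  its <- gd$trimmed_mean_depth[gd$ref == names(its_ref)]
  mk <- gd[gd$ref != names(its_ref), , drop = FALSE]
  res <- estimate_cn_md(its, mk, genome_id)
  res$gene_depths <- gd
  res
}
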