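# CN-HMM: ITS copy number from a genome assembly, by pairing LSU/SSU flank
# hits into ITS loci using the biological length window (400-800 bp, mean
# 550) and the contig-end rule for truncated copies.

#' Count ITS copies by pairing LSU and SSU flank hits
#'
#' Hits are paired greedily left-to-right, strand-aware: on the locus strand
#' the LSU flank lies upstream of the SSU flank, and the inner-edge gap
#' between the two hits (the ITS length) must lie within
#' `[min_gap, max_gap]`. Each hit is used at most once; when two candidate
#' partners are equidistant the higher bit score wins. An unpaired hit still
#' counts as one copy when the window where its partner would lie runs past
#' the contig end (within `end_window` of the boundary on the appropriate
#' side); such loci are flagged `end_truncated`.
#'
#' @param lsu_hits,ssu_hits hit tables from [scan_sequence()] (columns
#'   `contig`, `start`, `end`, `strand`, `score`, optionally `evalue`).
#' @param contig_lengths named integer vector of contig lengths.
#' @param min_gap,max_gap accepted ITS length window in bp (gaps of exactly
#'   `min_gap` or `max_gap` are accepted; 399 and 801 are not).
#' @param e_max E-value cutoff re-applied if hit tables carry `evalue`.
#' @param end_window distance from a contig end within which a missing
#'   partner is attributed to truncation (defaults to `max_gap`).
#' @param genome_id label stored in the result.
#' @return object of class `cn_hmm`: list with `genome`, `copy_number`,
#'   `loci` (data frame: contig, start, end, strand, completeness) and
#'   `params`.
#' @export
count_copies <- function(lsu_hits, ssu_hits, contig_lengths, min_gap = 400,
                         max_gap = 800, e_max = 0.001, end_window = max_gap,
                         genome_id = "genome") {
  stopifnot(min_gap > 0, min_gap < max_gap)
  filt <- function(h) {
    if (!nrow(h)) return(h)
    if ("evalue" %in% names(h)) h <- h[h$evalue <= e_max, , drop = FALSE]
    h[order(h$contig, h$start), , drop = FALSE]
  }
  lsu <- filt(lsu_hits); ssu <- filt(ssu_hits)

  # overlapping LSU/SSU intervals on the same contig: both discarded
  if (nrow(lsu) && nrow(ssu)) {
    drop_l <- logical(nrow(lsu)); drop_s <- logical(nrow(ssu))
    for (i in seq_len(nrow(lsu))) {
      ov <- ssu$contig == lsu$contig[i] & ssu$start < lsu$end[i] &
        lsu$start[i] < ssu$end
      if (any(ov)) { drop_l[i] <- TRUE; drop_s[ov] <- TRUE }
    }
    if (any(drop_l) || any(drop_s)) {
      warning(sum(drop_l), " LSU and ", sum(drop_s),
              " SSU hit(s) discarded due to LSU/SSU overlap")
      lsu <- lsu[!drop_l, , drop = FALSE]
      ssu <- ssu[!drop_s, , drop = FALSE]
    }
  }

  loci <- list()
  add_locus <- function(contig, start, end, strand, completeness) {
    loci[[length(loci) + 1]] <<- data.frame(
      contig = contig, start = start, end = end, strand = strand,
      completeness = completeness, stringsAsFactors = FALSE)
  }

  for (ctg in unique(c(lsu$contig, ssu$contig))) {
    clen <- contig_lengths[[ctg]]
    if (is.null(clen) || is.na(clen)) stop("unknown contig length for ", ctg)
    for (strand in c("+", "-")) {
      L <- lsu[lsu$contig == ctg & lsu$strand == strand, , drop = FALSE]
      S <- ssu[ssu$contig == ctg & ssu$strand == strand, , drop = FALSE]
      s_used <- logical(nrow(S))
      l_paired <- logical(nrow(L))
      ord <- if (strand == "+") order(L$start) else order(-L$start)
      for (i in ord) {
        gap <- if (strand == "+") S$start - L$end[i] else L$start[i] - S$end
        cand <- which(!s_used & gap >= min_gap & gap <= max_gap)
        if (!length(cand)) next
        best <- cand[order(gap[cand], -S$score[cand])][1]
        s_used[best] <- TRUE
        l_paired[i] <- TRUE
        if (strand == "+")
          add_locus(ctg, L$end[i], S$start[best], "+", "paired")
        else
          add_locus(ctg, S$end[best], L$start[i], "-", "paired")
      }
      # contig-end rule for unpaired hits: the partner window must overrun
      # the contig boundary on the side where the partner would sit
      for (i in which(!l_paired)) {
        trunc <- if (strand == "+") clen - L$end[i] < end_window
                 else L$start[i] < end_window
        if (trunc) {
          if (strand == "+")
            add_locus(ctg, L$end[i], min(clen, L$end[i] + max_gap), "+",
                      "end_truncated")
          else
            add_locus(ctg, max(0, L$start[i] - max_gap), L$start[i], "-",
                      "end_truncated")
        }
      }
      for (i in which(!s_used)) {
        trunc <- if (strand == "+") S$start[i] < end_window
                 else clen - S$end[i] < end_window
        if (trunc) {
          if (strand == "+")
            add_locus(ctg, max(0, S$start[i] - max_gap), S$start[i], "+",
                      "end_truncated")
          else
            add_locus(ctg, S$end[i], min(clen, S$end[i] + max_gap), "-",
                      "end_truncated")
        }
      }
    }
  }
  loci <- if (length(loci)) do.call(rbind, loci) else
    data.frame(contig = character(0), start = integer(0), end = integer(0),
               strand = character(0), completeness = character(0))
  loci <- loci[order(loci$contig, loci$start), , drop = FALSE]
  rownames(loci) <- NULL
  structure(list(genome = genome_id, copy_number = nrow(loci), loci = loci,
                 params = list(min_gap = min_gap, max_gap = max_gap,
                               e_max = e_max, end_window = end_window)),
            class = "cn_hmm")
}

#' @export
print.cn_hmm <- function(x, ...) {
  cat("CN-HMM result for ", x$genome, ": copy number ", x$copy_number,
      " (", sum(x$loci$completeness == "paired"), " paired, ",
      sum(x$loci$completeness == "end_truncated"), " end-truncated)\n",
      sep = "")
  invisible(x)
}

#' Extract ITS sequences for paired loci
#'
#' Returns one sequence per paired locus (the stretch between the two flank
#' hits); minus-strand loci are reverse-complemented. End-truncated loci are
#' excluded from the FASTA (with a message) but kept in the BED table.
#'
#' @param result a [count_copies()] result.
#' @param assembly named character vector of contigs (or `synthetic_genome`).
#' @return list with `seqs` (named character) and `bed` (data frame with BED
#'   columns contig, start, end, name, score, strand).
#' @export
extract_its <- function(result, assembly) {
  stopifnot(inherits(result, "cn_hmm"))
  if (inherits(assembly, "synthetic_genome")) assembly <- assembly$contigs
  loci <- result$loci
  if (nrow(loci)) {
    clen <- nchar(assembly)[loci$contig]
    if (any(loci$start < 0 | loci$end > clen))
      stop("locus outside contig bounds")
  }
  keep <- loci$completeness == "paired"
  if (any(!keep))
    message(sum(!keep), " end-truncated locus/loci excluded from FASTA")
  seqs <- character(0)
  if (any(keep)) {
    p <- loci[keep, , drop = FALSE]
    seqs <- substring(assembly[p$contig], p$start + 1, p$end)
    minus <- p$strand == "-"
    seqs[minus] <- revcomp(seqs[minus])
    names(seqs) <- sprintf("%s_its%d", result$genome, seq_len(nrow(p)))
  }
  bed <- data.frame(contig = loci$contig, start = loci$start, end = loci$end,
                    name = sprintf("%s_locus%d", result$genome, seq_len(nrow(loci))),
                    score = rep(0, nrow(loci)), strand = loci$strand,
                    stringsAsFactors = FALSE)
  list(seqs = seqs, bed = bed)
}

#' Run the full CN-HMM pipeline on one assembly
#'
#' Scans both flank profiles, applies the E-value filter and pairing rules,
#' and returns the copy-number result together with the extracted ITS
#' sequences.
#'
#' @param assembly named character vector of contigs or a
#'   `synthetic_genome`.
#' @param lsu_profile,ssu_profile `profile_hmm` models of the two flanks.
#' @param e_max,min_gap,max_gap,end_window see [count_copies()].
#' @param lsu_calibration,ssu_calibration optional precomputed
#'   [calibrate_profile()] results, reused across genomes.
#' @param genome_id label for the result.
#' @return a `cn_hmm` object with an extra `its` element
#'   (see [extract_its()]).
#' @export
cn_hmm <- function(assembly, lsu_profile, ssu_profile, e_max = 0.001,
                   min_gap = 400, max_gap = 800, end_window = max_gap,
                   lsu_calibration = NULL, ssu_calibration = NULL,
                   genome_id = "genome") {
  if (inherits(assembly, "synthetic_genome")) assembly <- assembly$contigs
  lsu_hits <- scan_sequence(lsu_profile, assembly, e_max, lsu_calibration)
  ssu_hits <- scan_sequence(ssu_profile, assembly, e_max, ssu_calibration)
  res <- count_copies(lsu_hits, ssu_hits, nchar(assembly), min_gap, max_gap,
                      e_max, end_window, genome_id)
  res$its <- extract_its(res, assembly)
  res
}
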