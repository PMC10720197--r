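# Nucleotide profile HMMs for the rRNA flanks of the ITS region: model
# construction from a multiple alignment, local Viterbi search of assemblies
# on both strands, and E-value calibration on shuffled sequence.

.base_idx <- function(x) {
  # character string -> 0..3 integer vector, -1 for ambiguity codes
  v <- utf8ToInt(toupper(x))
  out <- rep.int(-1L, length(v))
  out[v == 65L] <- 0L # A
  out[v == 67L] <- 1L # C
  out[v == 71L] <- 2L # G
  out[v == 84L] <- 3L # T
  out
}

#' Build a nucleotide profile HMM from a multiple alignment
#'
#' Match states are the alignment columns with fewer than 50% gaps. Match
#' emissions are estimated from the observed base counts with +1
#' pseudocounts; per-position match/insert/delete transitions likewise.
#' Insert emissions equal the background, so inserted bases are neutral in
#' log-odds scoring.
#'
#' @param alignment character vector of >= 2 aligned sequences of equal
#'   width (gaps `-` or `.`), e.g. from [read_alignment()].
#' @param name model label (conventionally `"LSU"` or `"SSU"`).
#' @return object of class `profile_hmm` with elements `M`,
#'   `match_emissions` (4 x M), `insert_emissions`, `transitions`
#'   (M x 7: MM, MI, MD, IM, II, DM, DD), `background`, `name`.
#' @export
build_profile <- function(alignment, name = "profile") {
  alignment <- toupper(as.character(alignment))
  if (length(alignment) < 2)
    stop("an alignment of at least 2 sequences is required")
  w <- nchar(alignment)
  if (length(unique(w)) != 1) stop("ragged alignment: unequal widths")
  n <- length(alignment)
  mat <- matrix(unlist(strsplit(chartr(".", "-", alignment), "", fixed = TRUE)),
                nrow = n, byrow = TRUE)
  gapfrac <- colMeans(mat == "-")
  match_cols <- which(gapfrac < 0.5)
  M <- length(match_cols)
  if (M < 1) stop("no match columns (every column is >= 50% gaps)")

  counts <- function(col) {
    v <- mat[, col]
    c(sum(v == "A"), sum(v == "C"), sum(v == "G"), sum(v == "T"))
  }
  em <- vapply(match_cols, function(col) {
    cc <- counts(col)
    (cc + 1) / (sum(cc) + 4)
  }, numeric(4))
  rownames(em) <- DNA

  allc <- c(sum(mat == "A"), sum(mat == "C"), sum(mat == "G"), sum(mat == "T"))
  background <- (allc + 1) / (sum(allc) + 4)
  names(background) <- DNA

  # per-sequence state path over match columns: M (base) or D (gap); insert
  # columns with a base emit I between flanking match states
  is_match <- logical(ncol(mat)); is_match[match_cols] <- TRUE
  tc <- matrix(0, M, 7,
               dimnames = list(NULL, c("MM", "MI", "MD", "IM", "II", "DM", "DD")))
  for (s in seq_len(n)) {
    v <- mat[s, ]
    state <- character(0); posn <- integer(0)
    j <- 0
    for (col in seq_len(ncol(mat))) {
      if (is_match[col]) {
        j <- j + 1
        state <- c(state, if (v[col] == "-") "D" else "M"); posn <- c(posn, j)
      } else if (v[col] != "-") {
        state <- c(state, "I"); posn <- c(posn, j)
      }
    }
    if (length(state) < 2) next
    for (k in seq_len(length(state) - 1)) {
      from <- state[k]; to <- state[k + 1]; at <- max(posn[k], 1L)
      lab <- paste0(from, to)
      if (lab %in% colnames(tc) && at <= M) tc[at, lab] <- tc[at, lab] + 1
    }
  }
  tr <- tc + 1 # pseudocounts
  tr[, c("MM", "MI", "MD")] <- tr[, c("MM", "MI", "MD")] /
    rowSums(tr[, c("MM", "MI", "MD")])
  tr[, c("IM", "II")] <- tr[, c("IM", "II")] / rowSums(tr[, c("IM", "II")])
  tr[, c("DM", "DD")] <- tr[, c("DM", "DD")] / rowSums(tr[, c("DM", "DD")])

  structure(list(M = M, match_emissions = em, insert_emissions = background,
                 transitions = tr, background = background, name = name),
            class = "profile_hmm")
}

#' @export
print.profile_hmm <- function(x, ...) {
  cat("Profile HMM '", x$name, "': ", x$M, " match states\n", sep = "")
  invisible(x)
}

# log2-odds scoring tables used by the scanner
.profile_tables <- function(profile) {
  msc <- log2(sweep(profile$match_emissions, 1, profile$background, `/`))
  tr <- log2(profile$transitions)
  list(msc = msc, tr = tr, begin = -log2(profile$M))
}

#' Scan sequences with a profile HMM
#'
#' Local Viterbi alignment of the profile against both strands of every
#' contig. Bit scores are log2-odds of the aligned window under the profile
#' versus the background; E-values follow `E = K * N * 2^-score` with the
#' database length `N` counting both strands and `K` calibrated on shuffled
#' sequence (see [calibrate_profile()]). Per strand, overlapping alignments
#' are resolved greedily by score. Coordinates are reported on the forward
#' strand, 0-based half-open.
#'
#' @param profile a [build_profile()] model.
#' @param seqs named character vector of contigs (or a `synthetic_genome`).
#' @param e_max E-value cutoff; hits above it are dropped (the pipeline
#'   default is 0.001).
#' @param calibration optional result of [calibrate_profile()]; computed from
#'   `seqs` when `NULL`. Pass a precomputed calibration when scanning many
#'   genomes with one profile.
#' @param seed seed used when calibrating internally.
#' @return data frame with columns `contig`, `start`, `end`, `strand`,
#'   `score`, `evalue`, sorted by contig and start.
#' @export
scan_sequence <- function(profile, seqs, e_max = 0.001, calibration = NULL,
                          seed = 1) {
  stopifnot(inherits(profile, "profile_hmm"))
  if (profile$M < 1) stop("empty profile")
  if (inherits(seqs, "synthetic_genome")) seqs <- seqs$contigs
  if (!length(seqs) || any(nchar(seqs) == 0)) stop("empty assembly")
  if (is.null(names(seqs))) names(seqs) <- paste0("contig", seq_along(seqs))
  tab <- .profile_tables(profile)
  if (is.null(calibration))
    calibration <- calibrate_profile(profile, seqs, seed = seed)
  K <- calibration$K
  N <- 2 * sum(nchar(seqs))
  score_min <- log2(K * N / e_max)

  out <- list()
  for (ci in seq_along(seqs)) {
    L <- nchar(seqs[[ci]])
    for (strand in c("+", "-")) {
      s <- if (strand == "+") seqs[[ci]] else revcomp(seqs[[ci]])
      res <- viterbi_scan_cpp(.base_idx(s), tab$msc, tab$tr, tab$begin,
                              score_min)
      if (!length(res$start)) next
      st <- res$start; en <- res$end
      if (strand == "-") { tmp <- st; st <- L - en; en <- L - tmp }
      out[[length(out) + 1]] <- data.frame(
        contig = names(seqs)[ci], start = st, end = en, strand = strand,
        score = res$score, evalue = K * N * 2^(-res$score),
        stringsAsFactors = FALSE)
    }
  }
  if (!length(out))
    return(data.frame(contig = character(0), start = integer(0),
                      end = integer(0), strand = character(0),
                      score = numeric(0), evalue = numeric(0)))
  hits <- do.call(rbind, out)
  hits <- hits[hits$evalue <= e_max, , drop = FALSE]
  hits <- hits[order(hits$contig, hits$start), , drop = FALSE]
  rownames(hits) <- NULL
  hits
}

# chunked dinucleotide shuffle: permute non-overlapping 2-mers, preserving
# the dinucleotide composition up to chunk junctions
.dinuc_shuffle <- function(x) {
  n <- nchar(x)
  n2 <- n - n %% 2
  starts <- seq(1, n2, by = 2)
  chunks <- substring(x, starts, starts + 1)
  paste(c(sample(chunks), if (n > n2) substr(x, n, n)), collapse = "")
}

#' Calibrate the E-value constant of a profile
#'
#' Fits the Gumbel tail `P(S_max > s) = 1 - exp(-K N 2^-s)` with the decay
#' fixed at lambda = ln 2, estimating `K` by maximum likelihood from the top
#' scores of scans of dinucleotide-shuffled copies of the target sequence
#' (`K_hat = n / (N * sum(2^-s_i))`). Only the E <= e_max filter semantics
#' are contractual; the constant itself is an empirical calibration.
#'
#' @param profile a `profile_hmm`.
#' @param seqs sequences to shuffle (a sample is taken up to `sample_len`
#'   bases); random background sequence is used when `NULL`.
#' @param n_shuffle number of shuffled replicates.
#' @param sample_len maximum calibration sequence length.
#' @param seed integer seed.
#' @return list with elements `K`, `scores`, `n_bases`.
#' @export
calibrate_profile <- function(profile, seqs = NULL, n_shuffle = 4,
                              sample_len = 50000, seed = 1) {
  set.seed(seed)
  if (inherits(seqs, "synthetic_genome")) seqs <- seqs$contigs
  base <- if (is.null(seqs)) .random_dna(sample_len) else
    substr(paste(seqs, collapse = ""), 1, sample_len)
  tab <- .profile_tables(profile)
  scores <- vapply(seq_len(n_shuffle), function(i) {
    sh <- .dinuc_shuffle(base)
    max(viterbi_scan_cpp(.base_idx(sh), tab$msc, tab$tr, tab$begin,
                         1e9)$max_score,
        viterbi_scan_cpp(.base_idx(revcomp(sh)), tab$msc, tab$tr, tab$begin,
                         1e9)$max_score)
  }, numeric(1))
  N <- 2 * nchar(base)
  K <- n_shuffle / (N * sum(2^(-scores)))
  list(K = K, scores = scores, n_bases = N)
}
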