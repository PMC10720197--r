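# Synthetic-data generators: genomes with known rDNA tandem arrays, shotgun
# and copy-number-weighted ITS amplicon reads, compositional count matrices
# with controlled basis correlations, and longitudinal diet tables. Every
# generator is deterministic for a given seed.

#' Default rDNA flank templates
#'
#' Fixed pseudo-random LSU and SSU flank template sequences at the profile
#' lengths used for the real rRNA flanks (588 bp for the LSU side, 142 bp for
#' the SSU side). Generated from an internal fixed seed so the defaults are
#' stable across sessions.
#'
#' @param lsu_length,ssu_length template lengths in bp.
#' @return list with elements `lsu` and `ssu` (character).
#' @export
flank_templates <- function(lsu_length = 588, ssu_length = 142) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(76143)
  list(lsu = .random_dna(lsu_length), ssu = .random_dna(ssu_length))
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv()))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}

#' Simulate a gap-free alignment by mutating a template
#'
#' Generates independently diverged copies of a template sequence, a stand-in
#' for the curated flank alignments a profile HMM is normally built from.
#'
#' @param template character sequence.
#' @param n number of sequences.
#' @param divergence per-base substitution probability.
#' @param seed integer seed.
#' @return character vector of `n` equal-length sequences.
#' @export
simulate_alignment <- function(template, n = 10, divergence = 0.02, seed = 1) {
  set.seed(seed)
  vapply(seq_len(n), function(i) .mutate_seq(template, divergence),
         character(1))
}

#' Specify a synthetic genome with planted rDNA arrays
#'
#' Each array is `copies` repeats of the unit
#' LSU flank / ITS spacer / SSU flank / inter-copy spacer, planted at a given
#' contig position. Flank copies are mutated independently at
#' `flank_divergence`; the ITS spacer of an array is a fixed random sequence
#' shared by all its copies (reads from different copies must map to one ITS
#' reference). Single-copy marker genes are planted outside the arrays.
#'
#' @param contig_lengths integer vector of contig lengths (bp).
#' @param arrays data frame with columns `contig` (1-based index), `start`
#'   (0-based), `copies` (>= 1), `spacer` (bp between copies); optional
#'   column `its_length` overriding the global value per array.
#' @param its_length ITS spacer length in bp (400-800 is the biological
#'   range; default 550, the canonical average).
#' @param flank_divergence per-base substitution probability applied to each
#'   planted flank copy, in `[0, 1)`.
#' @param templates list with `lsu` and `ssu` template sequences
#'   (see [flank_templates()]).
#' @param truncate_last_copy if `TRUE`, the contig holding the last array is
#'   cut mid-ITS of that array's last copy, so its SSU flank is absent and
#'   the copy is only detectable through the contig-end rule.
#' @param n_markers,marker_length number and length of single-copy marker
#'   genes planted per genome.
#' @param seed integer seed; identical seeds give identical genomes.
#' @return object of class `genome_spec`.
#' @export
genome_spec <- function(contig_lengths, arrays, its_length = 550,
                        flank_divergence = 0, templates = flank_templates(),
                        truncate_last_copy = FALSE, n_markers = 0,
                        marker_length = 1000, seed = 1) {
  arrays <- as.data.frame(arrays)
  stopifnot(all(c("contig", "start", "copies", "spacer") %in% names(arrays)))
  if (!"its_length" %in% names(arrays)) arrays$its_length <- its_length
  arrays$its_length[is.na(arrays$its_length)] <- its_length
  .check_scalar_num(flank_divergence, "flank_divergence", 0, 1 - 1e-9)
  if (any(arrays$copies < 0)) stop("copy numbers must be >= 0")
  structure(list(contig_lengths = as.integer(contig_lengths), arrays = arrays,
                 its_length = its_length, flank_divergence = flank_divergence,
                 templates = templates,
                 truncate_last_copy = isTRUE(truncate_last_copy),
                 n_markers = n_markers, marker_length = marker_length,
                 seed = as.integer(seed)),
            class = "genome_spec")
}

#' Synthesize a genome assembly with ground truth
#'
#' Builds the contigs described by a [genome_spec()] and records every
#' planted ITS locus (0-based half-open coordinates) and marker gene.
#'
#' @param spec a `genome_spec`.
#' @return list of class `synthetic_genome` with elements
#'   `contigs` (named character), `truth` (list: `copy_number`, `loci` data
#'   frame with columns contig/start/end/strand/flag, `marker_loci`),
#'   `its_seqs` (one ITS sequence per array), `marker_seqs`.
#' @export
synthesize_genome <- function(spec) {
  stopifnot(inherits(spec, "genome_spec"))
  set.seed(spec$seed)
  lsu <- spec$templates$lsu
  ssu <- spec$templates$ssu
  nl <- nchar(lsu); ns <- nchar(ssu)
  contigs <- vapply(spec$contig_lengths, .random_dna, character(1))
  names(contigs) <- paste0("contig", seq_along(contigs))
  occupied <- vector("list", length(contigs)) # list of [start,end) matrices

  loci <- list(); its_seqs <- character(0)
  arrays <- spec$arrays
  for (a in seq_len(nrow(arrays))) {
    ci <- arrays$contig[a]
    itsl <- arrays$its_length[a]
    unit <- nl + itsl + ns + arrays$spacer[a]
    alen <- arrays$copies[a] * unit - arrays$spacer[a]
    s0 <- arrays$start[a]
    if (s0 < 0 || s0 + alen > spec$contig_lengths[ci])
      stop("array ", a, " out of contig bounds")
    for (occ in occupied[[ci]])
      if (s0 < occ[2] && occ[1] < s0 + alen) stop("planted features overlap")
    occupied[[ci]] <- c(occupied[[ci]], list(c(s0, s0 + alen)))
    its <- .random_dna(itsl)
    its_seqs <- c(its_seqs, setNames(its, paste0("array", a)))
    seq_chunks <- character(0)
    pos <- s0
    for (k in seq_len(arrays$copies[a])) {
      lsu_k <- .mutate_seq(lsu, spec$flank_divergence)
      ssu_k <- .mutate_seq(ssu, spec$flank_divergence)
      seq_chunks <- c(seq_chunks, lsu_k, its, ssu_k,
                      if (k < arrays$copies[a]) .random_dna(arrays$spacer[a]))
      loci[[length(loci) + 1]] <- data.frame(
        contig = names(contigs)[ci], start = pos + nl, end = pos + nl + itsl,
        strand = "+", flag = "paired", array = a, stringsAsFactors = FALSE)
      pos <- pos + unit
    }
    block <- paste(seq_chunks, collapse = "")
    stopifnot(nchar(block) == alen)
    ctg <- contigs[[ci]]
    contigs[[ci]] <- paste0(substr(ctg, 1, s0), block,
                            substr(ctg, s0 + alen + 1, nchar(ctg)))
  }
  loci <- if (length(loci)) do.call(rbind, loci) else
    data.frame(contig = character(0), start = integer(0), end = integer(0),
               strand = character(0), flag = character(0), array = integer(0))

  if (spec$truncate_last_copy && nrow(loci)) {
    # cut the contig mid-ITS of the last planted copy: its SSU flank (and the
    # second half of its ITS) fall off the contig end
    last <- loci[nrow(loci), ]
    cut_at <- last$start + floor((last$end - last$start) / 2)
    ci <- which(names(contigs) == last$contig)
    contigs[[ci]] <- substr(contigs[[ci]], 1, cut_at)
    loci$end[nrow(loci)] <- cut_at
    loci$flag[nrow(loci)] <- "end_truncated"
    occupied[[ci]] <- lapply(occupied[[ci]], function(o) pmin(o, cut_at))
  }

  marker_loci <- data.frame(contig = character(0), start = integer(0),
                            end = integer(0), gene = character(0))
  marker_seqs <- character(0)
  if (spec$n_markers > 0) {
    free_ci <- seq_along(contigs)
    placed <- 0; tries <- 0
    while (placed < spec$n_markers && tries < 2000) {
      tries <- tries + 1
      ci <- sample(free_ci, 1)
      L <- nchar(contigs[[ci]])
      if (L < spec$marker_length) next
      s0 <- sample.int(L - spec$marker_length + 1, 1) - 1
      ok <- TRUE
      for (occ in occupied[[ci]])
        if (s0 < occ[2] && occ[1] < s0 + spec$marker_length) { ok <- FALSE; break }
      if (!ok) next
      g <- .random_dna(spec$marker_length)
      contigs[[ci]] <- paste0(substr(contigs[[ci]], 1, s0), g,
                              substr(contigs[[ci]], s0 + spec$marker_length + 1, L))
      occupied[[ci]] <- c(occupied[[ci]], list(c(s0, s0 + spec$marker_length)))
      placed <- placed + 1
      id <- paste0("marker", placed)
      marker_loci <- rbind(marker_loci, data.frame(
        contig = names(contigs)[ci], start = s0, end = s0 + spec$marker_length,
        gene = id, stringsAsFactors = FALSE))
      marker_seqs[id] <- g
    }
    if (placed < spec$n_markers)
      stop("could not place all marker genes without overlap")
  }

  structure(list(contigs = contigs,
                 truth = list(copy_number = nrow(loci), loci = loci,
                              marker_loci = marker_loci),
                 its_seqs = its_seqs, marker_seqs = marker_seqs, spec = spec),
            class = "synthetic_genome")
}

#' @export
print.synthetic_genome <- function(x, ...) {
  cat("Synthetic genome:", length(x$contigs), "contig(s),",
      sum(nchar(x$contigs)), "bp;",
      x$truth$copy_number, "planted ITS copies;",
      nrow(x$truth$marker_loci), "marker genes\n")
  invisible(x)
}

# read simulation -------------------------------------------------------------

# sample reads from one sequence set; lengths-proportional over contigs
.sim_reads_from <- function(seqs, weights, n_reads, read_length, error_rate,
                            prefix) {
  lens <- nchar(seqs)
  valid <- lens >= read_length
  if (!any(valid)) stop("no sequence is at least one read length long")
  if (any(!valid))
    warning(sum(!valid), " sequence(s) shorter than the read length skipped")
  seqs <- seqs[valid]; lens <- lens[valid]; weights <- weights[valid]
  nvalid <- lens - read_length + 1
  prob <- weights / sum(weights)
  src <- sample.int(length(seqs), n_reads, replace = TRUE, prob = prob)
  start <- floor(runif(n_reads) * nvalid[src]) # 0-based
  fwd <- runif(n_reads) < 0.5
  out <- substring(seqs[src], start + 1, start + read_length)
  out[!fwd] <- revcomp(out[!fwd])
  if (error_rate > 0) {
    nb <- n_reads * read_length
    err <- which(runif(nb) < error_rate)
    if (length(err)) {
      ri <- (err - 1) %/% read_length + 1
      pp <- (err - 1) %% read_length + 1
      for (k in seq_along(err)) {
        b <- substr(out[ri[k]], pp[k], pp[k])
        substr(out[ri[k]], pp[k], pp[k]) <- sample(setdiff(DNA, b), 1)
      }
    }
  }
  data.frame(id = sprintf("%s_%06d", prefix, seq_len(n_reads)),
             seq = out, qual = strrep("I", read_length),
             src = names(seqs)[src], src_pos = start,
             src_strand = ifelse(fwd, "+", "-"), stringsAsFactors = FALSE)
}

#' Simulate shotgun reads
#'
#' Single-end reads with uniform start positions, uniform strand, i.i.d.
#' substitution errors and constant quality strings. For a single assembly,
#' reads are allocated across contigs proportionally to contig length; for a
#' [mock_community()], across genomes proportionally to
#' abundance x genome length.
#'
#' @param x named character vector of contigs, a `synthetic_genome`, or a
#'   `mock_community`.
#' @param n_reads number of reads.
#' @param read_length read length in bp.
#' @param error_rate per-base substitution probability.
#' @param seed integer seed.
#' @return data frame with columns `id`, `seq`, `qual` plus source-of-truth
#'   columns `src`, `src_pos`, `src_strand`.
#' @export
simulate_shotgun_reads <- function(x, n_reads, read_length = 100,
                                   error_rate = 0.005, seed = 1) {
  .check_scalar_num(error_rate, "error_rate", 0, 1 - 1e-9)
  if (n_reads < 0) stop("n_reads must be >= 0")
  set.seed(seed)
  if (inherits(x, "synthetic_genome")) x <- x$contigs
  if (inherits(x, "mock_community")) {
    glen <- vapply(x$genomes, function(g) sum(nchar(g)), numeric(1))
    w <- x$members$abundance * glen[x$members$taxon]
    seqs <- vapply(x$genomes[x$members$taxon], paste, character(1), collapse = "")
    names(seqs) <- x$members$taxon
    return(.sim_reads_from(seqs, w, n_reads, read_length, error_rate, "wgs"))
  }
  stopifnot(is.character(x), all(nchar(x) > 0))
  .sim_reads_from(x, nchar(x), n_reads, read_length, error_rate, "wgs")
}

#' Simulate ITS amplicon reads
#'
#' Reads are drawn from the members' ITS sequences with sampling weight
#' proportional to abundance x ITS copy number: the copy-number bias that
#' distorts amplicon-based mycobiome profiles.
#'
#' @param community a [mock_community()] (members need positive `cn`).
#' @param its_seqs named character vector of ITS sequences, one per member
#'   taxon.
#' @inheritParams simulate_shotgun_reads
#' @return data frame as in [simulate_shotgun_reads()].
#' @export
simulate_its_amplicons <- function(community, its_seqs, n_reads,
                                   read_length = 100, error_rate = 0.005,
                                   seed = 1) {
  set.seed(seed)
  m <- community$members
  missing <- setdiff(m$taxon, names(its_seqs))
  if (length(missing))
    stop("missing ITS sequence for member(s): ", paste(missing, collapse = ", "))
  if (any(m$cn <= 0)) stop("all members must have cn > 0")
  w <- m$abundance * m$cn
  .sim_reads_from(setNames(its_seqs[m$taxon], m$taxon), w, n_reads,
                  read_length, error_rate, "its")
}

# compositional counts ---------------------------------------------------------

#' Simulate compositional counts with known basis correlations
#'
#' Log-normal basis abundances with a requested correlation structure are
#' closed to fixed sequencing depth by multinomial sampling, the regime SparCC
#' is designed for. The true basis correlation matrix is returned alongside.
#'
#' @param n_samples,n_taxa dimensions.
#' @param basis_corr either `NULL` (identity), a full correlation matrix, or
#'   a data frame with columns `i`, `j`, `rho` of planted pairwise basis
#'   correlations (all other off-diagonals 0).
#' @param depth total count per sample (row sum).
#' @param mu_sd spread of per-taxon log-mean abundances (controls unevenness).
#' @param sigma log-scale standard deviation of the basis.
#' @param seed integer seed.
#' @return list with `counts` (n_samples x n_taxa matrix, each row summing to
#'   `depth`), `basis_corr` (the truth), and `log_basis`.
#' @export
simulate_compositional_counts <- function(n_samples, n_taxa, basis_corr = NULL,
                                          depth = 5e4, mu_sd = 1, sigma = 1,
                                          seed = 1) {
  if (depth <= 0) stop("depth must be > 0")
  R <- diag(n_taxa)
  if (is.data.frame(basis_corr)) {
    for (k in seq_len(nrow(basis_corr))) {
      i <- basis_corr$i[k]; j <- basis_corr$j[k]
      R[i, j] <- R[j, i] <- basis_corr$rho[k]
    }
  } else if (is.matrix(basis_corr)) {
    R <- basis_corr
  }
  ch <- tryCatch(chol(R), error = function(e)
    stop("basis correlation specification is not positive-definite"))
  set.seed(seed)
  mu <- rnorm(n_taxa, 0, mu_sd)
  Z <- matrix(rnorm(n_samples * n_taxa), n_samples) %*% ch
  logb <- sweep(sigma * Z, 2, mu, `+`)
  p <- exp(logb)
  p <- p / rowSums(p)
  counts <- t(apply(p, 1, function(pr) rmultinom(1, depth, pr)[, 1]))
  dimnames(counts) <- list(paste0("s", seq_len(n_samples)),
                           paste0("t", seq_len(n_taxa)))
  colnames(logb) <- colnames(counts)
  list(counts = counts, basis_corr = R, log_basis = logb)
}

# diet tables ------------------------------------------------------------------

#' Simulate longitudinal diet questionnaire tables
#'
#' Per-subject habitual baselines with timepoint noise. Energy is correlated
#' with the macronutrient columns by construction (each nutrient is a fixed
#' fraction of energy plus subject- and timepoint-level noise); food-group
#' columns are weekly frequencies.
#'
#' @param n_subjects,n_timepoints design shape (the study design was 6
#'   subjects x 2 administrations = 12 questionnaires).
#' @param n_nutrients number of nutrient columns (besides energy).
#' @param n_food_groups number of food-group frequency columns.
#' @param noise_sd relative timepoint noise (0 = administrations identical).
#' @param seed integer seed.
#' @return data frame with columns `subject`, `timepoint`, `energy`,
#'   `nutrient_1..K`, `fg_1..G`; one row per (subject, timepoint).
#' @export
simulate_diet_profiles <- function(n_subjects, n_timepoints, n_nutrients = 6,
                                   n_food_groups = 5, noise_sd = 0.1,
                                   seed = 1) {
  stopifnot(n_subjects >= 1, n_timepoints >= 1)
  set.seed(seed)
  frac <- runif(n_nutrients, 0.02, 0.2) # nutrient share of energy
  energy0 <- rnorm(n_subjects, 2000, 300)
  nut0 <- outer(energy0, frac) * matrix(exp(rnorm(n_subjects * n_nutrients,
                                                  0, 0.15)), n_subjects)
  fg0 <- matrix(rpois(n_subjects * n_food_groups, 4), n_subjects)
  rows <- vector("list", n_subjects * n_timepoints)
  k <- 0
  for (tp in seq_len(n_timepoints)) for (s in seq_len(n_subjects)) {
    k <- k + 1
    e <- energy0[s] * (1 + noise_sd * rnorm(1))
    nut <- nut0[s, ] * (1 + noise_sd * rnorm(n_nutrients))
    fg <- pmax(0, fg0[s, ] + if (noise_sd > 0) rpois(n_food_groups, noise_sd * 4) -
                 round(noise_sd * 4) else 0)
    rows[[k]] <- c(subject = s, timepoint = tp, energy = e,
                   setNames(nut, paste0("nutrient_", seq_len(n_nutrients))),
                   setNames(fg, paste0("fg_", seq_len(n_food_groups))))
  }
  out <- as.data.frame(do.call(rbind, rows))
  out$subject <- as.integer(out$subject)
  out$timepoint <- as.integer(out$timepoint)
  out
}
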