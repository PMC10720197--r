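# Depth-based taxonomic profiling with the mock-community filters, diversity
# metrics, rarefaction, TMM normalization, enrichment ratios and the Stokes
# sedimentation calculator.

#' Convert per-gene mapping depths to a relative-abundance profile
#'
#' Hits with trimmed mean depth below `min_depth` are removed as possible
#' off-target mappings (the pipeline default of 15 was established for this
#' filtering). Each surviving hit's abundance is its depth divided by the sum
#' of all surviving depths; hits are then summed within the taxon at the
#' requested rank, and taxa outside `expected_taxa` are pooled into the
#' off-target mass.
#'
#' @param hits data frame with columns `gene`, `depth` and the rank columns
#'   (`species`, `genus`).
#' @param min_depth minimum mean depth kept (a hit at exactly `min_depth`
#'   survives; 14 does not at the default of 15).
#' @param level rank at which to aggregate.
#' @param expected_taxa known community members at that rank; `NULL` means
#'   everything is on-target.
#' @return object of class `abundance_profile`: list with `level`,
#'   `abundance` (named, on-target taxa) and `off_target_mass`; total mass 1.
#' @export
depth_profile_to_abundance <- function(hits, min_depth = 15,
                                       level = c("species", "genus"),
                                       expected_taxa = NULL) {
  level <- match.arg(level)
  if (!nrow(hits)) stop("no hits supplied")
  h <- hits[hits$depth >= min_depth, , drop = FALSE]
  if (!nrow(h)) stop("empty profile: every hit fell below the depth filter")
  share <- h$depth / sum(h$depth)
  taxon <- h[[level]]
  ab <- tapply(share, taxon, sum)
  ab <- setNames(as.numeric(ab), names(ab))
  off <- 0
  if (!is.null(expected_taxa)) {
    out <- !(names(ab) %in% expected_taxa)
    off <- sum(ab[out])
    ab <- ab[!out]
  }
  structure(list(level = level, abundance = ab, off_target_mass = off),
            class = "abundance_profile")
}

#' @export
print.abundance_profile <- function(x, ...) {
  cat("Abundance profile (", x$level, "): ", length(x$abundance),
      " taxa, off-target mass ", signif(x$off_target_mass, 3), "\n", sep = "")
  invisible(x)
}

# profile -> named numeric vector including the off-target leaf
.profile_vector <- function(p) {
  if (inherits(p, "abundance_profile")) {
    v <- p$abundance
    if (p$off_target_mass > 0) v <- c(v, off_target = p$off_target_mass)
    return(v)
  }
  p
}

#' TMM normalization factors
#'
#' Trimmed mean of M-values between-sample normalization (the standard
#' count-normalization for compositional sequencing libraries), computed by
#' edgeR with the canonical trim fractions. Factors are rescaled so their
#' geometric mean is 1.
#'
#' @param counts samples x features count matrix (>= 2 samples with positive
#'   totals).
#' @param logratio_trim,abs_trim trim fractions for log-ratios and absolute
#'   intensities.
#' @return list with `factors` (named, geometric mean 1), `lib_size`, and
#'   `scaled` (counts divided by effective library size, rescaled to the
#'   mean library).
#' @export
tmm_normalize <- function(counts, logratio_trim = 0.3, abs_trim = 0.05) {
  counts <- as.matrix(counts)
  if (nrow(counts) < 2) stop("TMM needs at least 2 samples")
  if (any(rowSums(counts) <= 0)) stop("every sample must have a positive total")
  f <- edgeR::calcNormFactors(t(counts), method = "TMM",
                              logratioTrim = logratio_trim,
                              sumTrim = abs_trim)
  lib <- rowSums(counts)
  eff <- lib * f
  scaled <- sweep(counts, 1, eff, `/`) * mean(lib)
  list(factors = setNames(f, rownames(counts)), lib_size = lib,
       scaled = scaled)
}

#' Alpha diversity: observed richness, Shannon, Chao1
#'
#' Shannon uses natural logarithms. Chao1 is `S + f1^2 / (2 f2)`, falling
#' back to the bias-corrected `S + f1 (f1 - 1) / (2 (f2 + 1))` when there are
#' no doubletons; it requires integer counts.
#'
#' @param x count vector, or a samples x features matrix (one result row per
#'   sample).
#' @return for a vector, a list with `observed`, `shannon`, `chao1`; for a
#'   matrix, a data frame.
#' @export
alpha_diversity <- function(x) {
  if (is.matrix(x) || is.data.frame(x)) {
    res <- t(apply(as.matrix(x), 1, function(r) unlist(alpha_diversity(r))))
    return(as.data.frame(res))
  }
  if (any(x < 0)) stop("negative entries")
  if (sum(x) == 0) {
    warning("empty sample: all diversity metrics set to 0")
    return(list(observed = 0, shannon = 0, chao1 = 0))
  }
  pos <- x[x > 0]
  S <- length(pos)
  p <- pos / sum(pos)
  shannon <- -sum(p * log(p))
  chao1 <- NA_real_
  if (all(abs(x - round(x)) < 1e-9)) {
    f1 <- sum(round(pos) == 1)
    f2 <- sum(round(pos) == 2)
    chao1 <- if (f2 > 0) S + f1^2 / (2 * f2) else S + f1 * (f1 - 1) / (2 * (f2 + 1))
  }
  list(observed = S, shannon = shannon, chao1 = chao1)
}

#' Bray-Curtis dissimilarity
#'
#' `1 - 2 * sum(min(p_i, q_i)) / sum(p_i + q_i)` over the union feature
#' space (features absent from one profile count as 0).
#'
#' @param p,q named (or equal-length) non-negative abundance vectors, or
#'   `abundance_profile` objects.
#' @return dissimilarity in `[0, 1]`.
#' @export
bray_curtis <- function(p, q) {
  p <- .profile_vector(p); q <- .profile_vector(q)
  if (!is.null(names(p)) || !is.null(names(q))) {
    feats <- union(names(p), names(q))
    p <- setNames(p[feats], feats); p[is.na(p)] <- 0
    q <- setNames(q[feats], feats); q[is.na(q)] <- 0
  }
  tot <- sum(p) + sum(q)
  if (tot == 0) stop("Bray-Curtis undefined: both profiles are all-zero")
  1 - 2 * sum(pmin(p, q)) / tot
}

#' Build a taxonomy tree from rank lineages
#'
#' Constructs a rooted tree with unit branch lengths from a lineage table
#' (e.g. kingdom, genus, species), the tree used for weighted UniFrac when no
#' phylogeny is available. An `off_target` tip attached directly under the
#' root can absorb pooled off-target mass without inventing a lineage.
#'
#' @param lineage data frame whose columns are ranks from coarsest to
#'   finest; the last column labels the tips.
#' @param add_off_target attach an `off_target` tip under the root.
#' @return an [ape::phylo] tree with unit branch lengths.
#' @export
lineage_tree <- function(lineage, add_off_target = TRUE) {
  lineage <- unique(as.data.frame(lineage))
  esc <- function(x) gsub("[(),:;\\s']", "_", x, perl = TRUE)
  build_multi <- function(df) {
    if (ncol(df) == 1) return(paste(paste0(esc(df[[1]]), ":1"), collapse = ","))
    groups <- split(df[-1], df[[1]], drop = TRUE)
    paste(vapply(names(groups), function(g)
      paste0("(", build_multi(groups[[g]]), "):1"), character(1)),
      collapse = ",")
  }
  nwk <- paste0("(", build_multi(lineage),
                if (add_off_target) ",off_target:1" else "", ");")
  ape::read.tree(text = nwk)
}

#' Weighted UniFrac distance
#'
#' Sum over branches of branch length times the absolute difference of the
#' abundance fractions descending through the branch; in the normalized form
#' the sum is divided by `sum(l_b * (A_b + B_b))`, bounding the distance to
#' `[0, 1]`.
#'
#' @param p,q abundance vectors named by tree tips (or
#'   `abundance_profile` objects; off-target mass maps to the
#'   `off_target` tip).
#' @param tree an [ape::phylo] tree containing every profiled taxon as a
#'   tip; `NULL` branch lengths default to 1.
#' @param normalized divide by the total weighted mass (default).
#' @return distance (>= 0; in `[0, 1]` when normalized).
#' @export
weighted_unifrac <- function(p, q, tree, normalized = TRUE) {
  p <- .profile_vector(p); q <- .profile_vector(q)
  tips <- tree$tip.label
  missing <- setdiff(union(names(p), names(q)), tips)
  if (length(missing))
    stop("taxa absent from tree: ", paste(missing, collapse = ", "))
  if (is.null(tree$edge.length)) tree$edge.length <- rep(1, nrow(tree$edge))
  pv <- setNames(numeric(length(tips)), tips); pv[names(p)] <- p
  qv <- setNames(numeric(length(tips)), tips); qv[names(q)] <- q
  if (sum(pv) == 0 || sum(qv) == 0) stop("profiles must have positive mass")
  pv <- pv / sum(pv); qv <- qv / sum(qv)

  tr <- ape::reorder.phylo(tree, "postorder")
  ntip <- length(tips)
  nnode <- tr$Nnode
  massA <- c(pv, numeric(nnode))
  massB <- c(qv, numeric(nnode))
  A <- B <- numeric(nrow(tr$edge))
  for (k in seq_len(nrow(tr$edge))) {
    par <- tr$edge[k, 1]; ch <- tr$edge[k, 2]
    A[k] <- massA[ch]; B[k] <- massB[ch]
    massA[par] <- massA[par] + massA[ch]
    massB[par] <- massB[par] + massB[ch]
  }
  num <- sum(tr$edge.length * abs(A - B))
  if (!normalized) return(num)
  den <- sum(tr$edge.length * (A + B))
  if (den == 0) return(0)
  num / den
}

#' Rarefaction curve by subsampling without replacement
#'
#' @param counts integer feature-count vector (reads per taxon).
#' @param depth_grid subsampling depths (each <= total reads).
#' @param n_reps subsampling replicates per depth.
#' @param seed integer seed.
#' @return data frame with columns `depth`, `richness` (mean observed
#'   features) and `pct` (percent of full-depth richness).
#' @export
rarefaction_curve <- function(counts, depth_grid, n_reps = 10, seed = 1) {
  counts <- round(counts)
  total <- sum(counts)
  if (any(depth_grid > total)) stop("subsampling depth exceeds total reads")
  set.seed(seed)
  cum <- cumsum(counts)
  full_rich <- sum(counts > 0)
  rows <- lapply(depth_grid, function(d) {
    rich <- vapply(seq_len(n_reps), function(r) {
      draw <- sample.int(total, d)
      length(unique(findInterval(draw - 1, cum) + 1))
    }, numeric(1))
    data.frame(depth = d, richness = mean(rich),
               pct = 100 * mean(rich) / full_rich)
  })
  do.call(rbind, rows)
}

#' Fungal enrichment ratio and fold change
#'
#' Per partition, the ratio of reads mapped to the fungal database over reads
#' mapped to the bacterial database; the fold change divides the fungal
#' partition's ratio by its matched control partition's ratio.
#'
#' @param fungal_enriched,bacterial_enriched per-sample mapped-read counts in
#'   the fungal-enriched partition.
#' @param fungal_control,bacterial_control matched counts in the control
#'   partition.
#' @return data frame with per-sample `ratio_enriched`, `ratio_control`,
#'   `fold` (NA and flagged when the control ratio is 0), plus a `mean_fold`
#'   attribute (arithmetic mean over defined folds).
#' @export
enrichment_ratio <- function(fungal_enriched, bacterial_enriched,
                             fungal_control, bacterial_control) {
  if (any(bacterial_enriched <= 0) || any(bacterial_control <= 0))
    stop("bacterial mapped counts must be positive in both partitions")
  re <- fungal_enriched / bacterial_enriched
  rc <- fungal_control / bacterial_control
  fold <- ifelse(rc > 0, re / rc, NA_real_)
  if (any(rc == 0)) warning("control ratio 0: fold undefined for some samples")
  out <- data.frame(ratio_enriched = re, ratio_control = rc, fold = fold)
  attr(out, "mean_fold") <- mean(fold, na.rm = TRUE)
  out
}

#' Stokes' law sedimentation calculator
#'
#' Solves `D = (18 eta ln(Rf/Ro) / ((rho_p - rho_f) omega^2 t))^0.5` for
#' whichever of `D` (particle diameter, cm), `omega` (rad/s) or `t` (s) is
#' left `NULL`; used to plan differential centrifugation of fungal versus
#' bacterial cells.
#'
#' @param D particle diameter (cm) or `NULL`.
#' @param eta fluid viscosity (poise).
#' @param Rf,Ro final and initial rotation radius (cm), `Rf > Ro`.
#' @param rho_p,rho_f particle and fluid density (g/ml).
#' @param omega rotational velocity (rad/s) or `NULL`.
#' @param t sedimentation time (s) or `NULL`.
#' @return the solved quantity (named numeric of length 1).
#' @export
stokes_solve <- function(D = NULL, eta, Rf, Ro, rho_p, rho_f, omega = NULL,
                         t = NULL) {
  unknown <- c(D = is.null(D), omega = is.null(omega), t = is.null(t))
  if (sum(unknown) != 1)
    stop("exactly one of D, omega, t must be NULL (the unknown)")
  for (v in list(eta = eta, Rf = Rf, Ro = Ro)) if (v <= 0)
    stop("eta, Rf, Ro must be positive")
  if (Rf <= Ro) stop("Rf must exceed Ro")
  drho <- rho_p - rho_f
  if (drho <= 0)
    stop("rho_p must exceed rho_f: the particle does not sediment")
  num <- 18 * eta * log(Rf / Ro)
  if (unknown[["D"]]) {
    return(c(D = sqrt(num / (drho * omega^2 * t))))
  }
  if (unknown[["t"]]) {
    return(c(t = num / (drho * omega^2 * D^2)))
  }
  c(omega = sqrt(num / (drho * t * D^2)))
}
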