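# Inter-kingdom co-abundance networks: SparCC compositional correlation,
# permutation p-values, network deconvolution, random-matrix-theory
# thresholding, graph construction, centralities, keystone selection and a
# discrete power-law degree fit.

#' SparCC compositional correlations
#'
#' Estimates basis correlations from compositional counts via logarithmically
#' scaled variances: fractions are estimated with a pseudocount, the
#' variation matrix `T_ij = var(log(x_i / x_j))` is computed, basis variances
#' are solved from the standard linear system, and strongly correlated pairs
#' are iteratively excluded from the approximation (one pair per round,
#' above `exclusion_threshold`, up to `max_exclusion_rounds`).
#'
#' @param counts samples x taxa count matrix (>= 4 taxa, >= 10 samples
#'   recommended).
#' @param n_inner_iter number of Dirichlet resamples when
#'   `use_dirichlet = TRUE`.
#' @param exclusion_threshold |rho| above which the strongest pair is
#'   excluded each round.
#' @param max_exclusion_rounds maximum exclusion rounds.
#' @param pseudocount added to counts for fraction estimation.
#' @param use_dirichlet average over Dirichlet-resampled fractions instead of
#'   the deterministic point estimate.
#' @param seed seed for Dirichlet resampling.
#' @return symmetric correlation matrix with unit diagonal, entries clipped
#'   to `[-1, 1]`.
#' @export
sparcc <- function(counts, n_inner_iter = 20, exclusion_threshold = 0.1,
                   max_exclusion_rounds = 10, pseudocount = 1,
                   use_dirichlet = FALSE, seed = NULL) {
  counts <- as.matrix(counts)
  p <- ncol(counts)
  if (p < 4) stop("SparCC needs at least 4 taxa (basis solution degenerate)")
  if (is.null(colnames(counts))) colnames(counts) <- paste0("t", seq_len(p))

  rho_from_logf <- function(logf) {
    V <- cov(logf)
    d <- diag(V)
    Tm <- outer(d, d, `+`) - 2 * V # variation matrix
    M <- matrix(1, p, p); diag(M) <- p - 1
    tvec <- rowSums(Tm)
    excl <- matrix(FALSE, p, p)
    for (round in seq_len(max_exclusion_rounds + 1)) {
      w2 <- solve(M, tvec)
      w2 <- pmax(w2, 1e-12)
      w <- sqrt(w2)
      rho <- (outer(w2, w2, `+`) - Tm) / (2 * outer(w, w))
      rho <- pmin(pmax(rho, -1), 1)
      diag(rho) <- 1
      if (round > max_exclusion_rounds) break
      cand <- abs(rho); cand[excl] <- 0; diag(cand) <- 0
      mx <- max(cand)
      if (mx <= exclusion_threshold) break
      ij <- which(cand == mx, arr.ind = TRUE)[1, ]
      i <- ij[1]; j <- ij[2]
      excl[i, j] <- excl[j, i] <- TRUE
      M[i, i] <- M[i, i] - 1; M[j, j] <- M[j, j] - 1
      M[i, j] <- M[j, i] <- 0
      tvec[i] <- tvec[i] - Tm[i, j]
      tvec[j] <- tvec[j] - Tm[i, j]
    }
    rho
  }

  if (!use_dirichlet) {
    f <- (counts + pseudocount) / rowSums(counts + pseudocount)
    rho <- rho_from_logf(log(f))
  } else {
    if (!is.null(seed)) set.seed(seed)
    acc <- matrix(0, p, p)
    for (it in seq_len(n_inner_iter)) {
      g <- matrix(stats::rgamma(length(counts), shape = counts + pseudocount),
                  nrow(counts))
      f <- g / rowSums(g)
      acc <- acc + rho_from_logf(log(f))
    }
    rho <- acc / n_inner_iter
    rho <- pmin(pmax(rho, -1), 1); diag(rho) <- 1
  }
  dimnames(rho) <- list(colnames(counts), colnames(counts))
  rho
}

#' Permutation p-values for a correlation matrix
#'
#' Null correlations are generated by independently permuting each taxon's
#' counts across samples and recomputing SparCC; two-sided p-values use the
#' add-one estimator `p = (1 + #{|rho_perm| >= |rho_obs|}) / (n_perm + 1)`,
#' so they are bounded below by `1 / (n_perm + 1)`.
#'
#' @param counts samples x taxa count matrix.
#' @param observed the observed SparCC matrix for `counts`.
#' @param n_perm number of permutations (>= 20).
#' @param seed integer seed.
#' @param ... passed on to [sparcc()].
#' @return symmetric p-value matrix (diagonal 1).
#' @export
permutation_pvalues <- function(counts, observed, n_perm = 100, seed = 1,
                                ...) {
  if (n_perm < 20) stop("n_perm must be >= 20")
  counts <- as.matrix(counts)
  set.seed(seed)
  exceed <- matrix(0, ncol(counts), ncol(counts))
  aobs <- abs(observed)
  for (b in seq_len(n_perm)) {
    perm <- apply(counts, 2, sample)
    rp <- sparcc(perm, ...)
    exceed <- exceed + (abs(rp) >= aobs)
  }
  pmat <- (1 + exceed) / (n_perm + 1)
  diag(pmat) <- 1
  dimnames(pmat) <- dimnames(observed)
  pmat
}

# eigen transform shared by deconvolution and its involution check
.nd_eigen_map <- function(G, f) {
  e <- eigen((G + t(G)) / 2, symmetric = TRUE)
  lam <- f(e$values)
  out <- e$vectors %*% (lam * t(e$vectors))
  (out + t(out)) / 2
}

#' Network deconvolution
#'
#' Removes transitively induced (indirect) correlations by the spectral
#' closure inverse: the observed matrix is linearly scaled so its largest
#' absolute eigenvalue is `beta`, each eigenvalue is mapped
#' `lambda -> lambda / (1 + lambda)`, and the matrix is reassembled.
#'
#' @param G_obs symmetric observed correlation matrix.
#' @param beta target spectral radius after scaling (in `(0, 1)`).
#' @param zero_diag zero the diagonal of the returned direct-effect matrix.
#' @return symmetric direct-effect matrix; attribute `scale` holds the
#'   applied scaling factor.
#' @export
network_deconvolution <- function(G_obs, beta = 0.99, zero_diag = TRUE) {
  G_obs <- as.matrix(G_obs)
  if (max(abs(G_obs - t(G_obs))) > 1e-8) stop("input must be symmetric")
  ev <- eigen((G_obs + t(G_obs)) / 2, symmetric = TRUE, only.values = TRUE)$values
  mx <- max(abs(ev))
  s <- if (mx > 0) beta / mx else 1
  Gs <- s * G_obs
  lam <- eigen(Gs, symmetric = TRUE, only.values = TRUE)$values
  if (any(abs(lam + 1) < 1e-12))
    stop("eigenvalue -1 after scaling: deconvolution transform is singular")
  D <- .nd_eigen_map(Gs, function(l) l / (1 + l))
  dimnames(D) <- dimnames(G_obs)
  if (zero_diag) diag(D) <- 0
  attr(D, "scale") <- s
  D
}

#' Random-matrix-theory correlation threshold
#'
#' For each candidate threshold, entries below it are zeroed and the
#' nearest-neighbour spacing distribution of the unfolded eigenvalues is
#' tested against the Poisson (exponential) form by a chi-square statistic.
#' The reported threshold is the smallest grid value whose spacing
#' distribution is Poisson-consistent and remains so over the next
#' `persistence` grid steps — the transition point at which random
#' (GOE-like) structure has been removed. Persistence is checked over a
#' short window rather than the whole remaining grid because thresholds
#' high enough to cut into genuine modules re-create random-looking
#' spacings. A spectrum too degenerate to test (almost no distinct
#' spacings left) counts as Poisson-consistent.
#'
#' @param rho symmetric correlation matrix (>= 20 taxa).
#' @param grid candidate thresholds.
#' @param p_cut chi-square p-value above which the Poisson fit is accepted.
#' @param n_bins spacing histogram bins.
#' @param persistence number of consecutive qualifying grid steps required.
#' @return the selected threshold (with attribute `pvals`); the grid maximum
#'   with a warning when no threshold qualifies.
#' @export
rmt_threshold <- function(rho, grid = seq(0.30, 0.95, by = 0.01),
                          p_cut = 0.05, n_bins = 20, persistence = 5) {
  rho <- as.matrix(rho)
  if (ncol(rho) < 20) stop("RMT thresholding needs at least 20 taxa")
  pvals <- vapply(grid, function(thr) .rmt_poisson_pvalue(rho, thr, n_bins),
                  numeric(1))
  ok <- pvals > p_cut
  qualifies <- vapply(seq_along(ok), function(i)
    all(ok[i:min(i + persistence - 1, length(ok))]), logical(1))
  if (!any(qualifies)) {
    warning("no threshold qualifies; returning the grid maximum")
    thr <- max(grid)
  } else {
    thr <- grid[which(qualifies)[1]]
  }
  attr(thr, "pvals") <- setNames(pvals, grid)
  thr
}

.rmt_poisson_pvalue <- function(rho, thr, n_bins) {
  A <- rho
  A[abs(A) < thr] <- 0
  diag(A) <- 1
  ev <- sort(eigen(A, symmetric = TRUE, only.values = TRUE)$values)
  # remove eigenvalue degeneracy: dense modules produce tight clusters of
  # near-identical eigenvalues that carry no spacing information; collapse
  # values closer than a small fraction of the spectral range
  tol <- max(1e-8, 1e-2 * (max(ev) - min(ev)))
  keep <- c(TRUE, diff(ev) > tol)
  ev <- ev[keep]
  n <- length(ev)
  if (n < 10) return(1) # nothing left to test: no random structure remains
  # spline unfolding of the cumulative spectral density
  df <- min(8, n - 2)
  fit <- tryCatch(smooth.spline(ev, seq_len(n), df = df),
                  error = function(e) NULL)
  if (is.null(fit)) return(1)
  unfolded <- predict(fit, ev)$y
  s <- diff(unfolded)
  s <- s[s > 0]
  if (length(s) < 10) return(1)
  s <- s / mean(s)
  brks <- c(seq(0, 3, length.out = n_bins), Inf)
  obs <- tabulate(findInterval(s, brks, rightmost.closed = FALSE),
                  nbins = n_bins)
  pe <- diff(stats::pexp(brks))
  expd <- length(s) * pe
  keep <- expd > 1e-12
  stat <- sum((obs[keep] - expd[keep])^2 / expd[keep])
  stats::pchisq(stat, df = sum(keep) - 1, lower.tail = FALSE)
}

#' Build a co-abundance network from correlations and p-values
#'
#' Benjamini-Hochberg adjustment is applied jointly over all unique pairs;
#' an edge is kept when `|rho| >= rho_min` *and* `fdr <= fdr_max` (at the
#' pipeline defaults, a pair at rho 0.77 is discarded however significant,
#' and a pair at FDR 0.01 is discarded however strong).
#'
#' @param rho symmetric correlation matrix (typically deconvolved SparCC).
#' @param p symmetric p-value matrix.
#' @param rho_min minimum |rho| (default 0.78, the RMT-derived threshold).
#' @param fdr_max maximum BH-adjusted p (default 0.001).
#' @param kingdom_map named character vector taxon -> kingdom.
#' @param keep_isolates keep nodes without edges.
#' @return object of class `cooccurrence_network`: list with `graph`
#'   (igraph), `edges` (from, to, rho, p, fdr, sign), `nodes`.
#' @export
build_network <- function(rho, p, rho_min = 0.78, fdr_max = 0.001,
                          kingdom_map = NULL, keep_isolates = FALSE) {
  rho <- as.matrix(rho); p <- as.matrix(p)
  stopifnot(all(dim(rho) == dim(p)))
  taxa <- colnames(rho)
  ut <- upper.tri(rho)
  idx <- which(ut, arr.ind = TRUE)
  fdr <- p.adjust(p[ut], method = "BH")
  keep <- abs(rho[ut]) >= rho_min & fdr <= fdr_max
  edges <- data.frame(from = taxa[idx[keep, 1]], to = taxa[idx[keep, 2]],
                      rho = rho[ut][keep], p = p[ut][keep], fdr = fdr[keep],
                      sign = ifelse(rho[ut][keep] >= 0, "positive", "negative"),
                      stringsAsFactors = FALSE)
  node_names <- if (keep_isolates) taxa else
    sort(unique(c(edges$from, edges$to)))
  nodes <- data.frame(taxon = node_names,
                      kingdom = if (is.null(kingdom_map)) NA_character_
                                else unname(kingdom_map[node_names]),
                      stringsAsFactors = FALSE)
  g <- igraph::graph_from_data_frame(edges, directed = FALSE,
                                     vertices = nodes)
  structure(list(graph = g, edges = edges, nodes = nodes,
                 params = list(rho_min = rho_min, fdr_max = fdr_max)),
            class = "cooccurrence_network")
}

#' @export
print.cooccurrence_network <- function(x, ...) {
  cat("Co-abundance network:", nrow(x$nodes), "nodes,", nrow(x$edges),
      "edges (", sum(x$edges$sign == "positive"), "positive,",
      sum(x$edges$sign == "negative"), "negative)\n")
  invisible(x)
}

#' Node centralities
#'
#' Degree, unnormalized shortest-path betweenness (raw path counts), and
#' closeness computed within each connected component as
#' `(n_component - 1) / sum(distances)`; singleton components get closeness
#' 0.
#'
#' @param net a [build_network()] result or an igraph graph.
#' @return data frame with columns `node`, `degree`, `betweenness`,
#'   `closeness`.
#' @export
centralities <- function(net) {
  g <- if (inherits(net, "cooccurrence_network")) net$graph else net
  if (igraph::vcount(g) == 0) stop("network is empty")
  deg <- igraph::degree(g)
  btw <- igraph::betweenness(g, directed = FALSE, normalized = FALSE)
  comp <- igraph::components(g)
  dmat <- igraph::distances(g)
  clo <- vapply(seq_len(igraph::vcount(g)), function(v) {
    memb <- comp$membership == comp$membership[v]
    n_c <- sum(memb)
    if (n_c <= 1) return(0)
    (n_c - 1) / sum(dmat[v, memb])
  }, numeric(1))
  data.frame(node = igraph::V(g)$name, degree = as.numeric(deg),
             betweenness = as.numeric(btw), closeness = clo,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Select keystone taxa
#'
#' Keystones are the taxa appearing in both the top-`k` list by node degree
#' and the top-`k` list by betweenness centrality; ties at rank `k` are all
#' included. The result is ordered by betweenness, then degree, then label.
#'
#' @param table a [centralities()] data frame.
#' @param k list depth (default 20).
#' @return character vector of keystone node labels.
#' @export
keystone_select <- function(table, k = 20) {
  if (!nrow(table)) stop("empty centrality table")
  top_by <- function(v) {
    cut <- sort(v, decreasing = TRUE)[min(k, length(v))]
    table$node[v >= cut]
  }
  keys <- intersect(top_by(table$degree), top_by(table$betweenness))
  t2 <- table[table$node %in% keys, , drop = FALSE]
  t2$node[order(-t2$betweenness, -t2$degree, t2$node)]
}

# generalized zeta function zeta(a, xmin) = sum_{k >= xmin} k^-a
.zeta_h <- function(a, xmin) {
  z <- pracma::zeta(a)
  if (xmin > 1) z <- z - sum(seq_len(xmin - 1)^(-a))
  z
}

#' Discrete power-law fit of a degree sequence
#'
#' Maximum-likelihood exponent of `P(k) = k^-alpha / zeta(alpha, xmin)` at
#' fixed `xmin`, with a Kolmogorov-Smirnov goodness-of-fit statistic against
#' the fitted law.
#'
#' @param degrees positive integer degree sequence (>= 10 values at or above
#'   `xmin`).
#' @param xmin minimum degree modelled.
#' @return object of class `powerlaw_fit`: list with `alpha`, `xmin`, `ks`,
#'   `n`, `degenerate`.
#' @export
powerlaw_fit <- function(degrees, xmin = 1) {
  x <- degrees[degrees >= xmin]
  if (length(x) < 10) stop("need at least 10 degrees >= xmin")
  if (any(x != round(x)) || any(x < 1)) stop("degrees must be positive integers")
  if (length(unique(x)) == 1) {
    return(structure(list(alpha = NA_real_, xmin = xmin, ks = NA_real_,
                          n = length(x), degenerate = TRUE),
                     class = "powerlaw_fit"))
  }
  slx <- sum(log(x))
  nll <- function(a) length(x) * log(.zeta_h(a, xmin)) + a * slx
  opt <- optimize(nll, c(1.000001, 12))
  alpha <- opt$minimum
  kmax <- max(x)
  pk <- (xmin:kmax)^(-alpha) / .zeta_h(alpha, xmin)
  cdf <- cumsum(pk)
  emp <- ecdf(x)(xmin:kmax)
  ks <- max(abs(emp - cdf))
  structure(list(alpha = alpha, xmin = xmin, ks = ks, n = length(x),
                 degenerate = FALSE), class = "powerlaw_fit")
}

#' @export
print.powerlaw_fit <- function(x, ...) {
  if (x$degenerate) cat("Power-law fit: degenerate (constant degrees)\n")
  else cat(sprintf("Power-law fit: alpha = %.3f (xmin = %d, KS = %.3f, n = %d)\n",
                   x$alpha, as.integer(x$xmin), x$ks, x$n))
  invisible(x)
}

#' Sample from a discrete power law
#'
#' @param n sample size.
#' @param alpha exponent (> 1).
#' @param xmin minimum value.
#' @param kmax truncation point (tail mass beyond it is folded into `kmax`).
#' @return integer vector of length `n`.
#' @export
rpowerlaw <- function(n, alpha, xmin = 1, kmax = 100000) {
  k <- xmin:kmax
  pk <- k^(-alpha)
  pk <- pk / sum(pk)
  sample(k, n, replace = TRUE, prob = pk)
}
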