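# Independent brute-force oracles used to validate the implementation paths.
# Each oracle is deliberately naive (enumeration / closed form) and shares no
# code with the functions it checks.

# --- exhaustive local-alignment score over the profile-HMM state space -------
# Enumerates every path that starts in a match state (uniform entry cost),
# moves through M/I/D transitions, and ends in a match state. seqi is a 0..3
# integer vector; msc 4 x M log2-odds; tr M x 7 log2 (MM MI MD IM II DM DD).
enum_viterbi_best <- function(seqi, msc, tr, begin_cost) {
  L <- length(seqi); M <- ncol(msc)
  best <- -Inf
  rec <- function(i, j, type, sc) {
    if (type == "M" && sc > best) best <<- sc
    if (type == "M") {
      if (i < L && j < M)
        rec(i + 1, j + 1, "M", sc + tr[j, "MM"] + msc[seqi[i + 1] + 1, j + 1])
      if (i < L) rec(i + 1, j, "I", sc + tr[j, "MI"])
      if (j < M) rec(i, j + 1, "D", sc + tr[j, "MD"])
    } else if (type == "I") {
      if (i < L && j < M)
        rec(i + 1, j + 1, "M", sc + tr[j, "IM"] + msc[seqi[i + 1] + 1, j + 1])
      if (i < L) rec(i + 1, j, "I", sc + tr[j, "II"])
    } else {
      if (i < L && j < M)
        rec(i + 1, j + 1, "M", sc + tr[j, "DM"] + msc[seqi[i + 1] + 1, j + 1])
      if (j < M) rec(i, j + 1, "D", sc + tr[j, "DD"])
    }
  }
  for (i0 in seq_len(L)) for (j0 in seq_len(M))
    rec(i0, j0, "M", begin_cost + msc[seqi[i0] + 1, j0])
  as.numeric(best)
}

# --- brute-force TMM factors (the edgeR algorithm re-derived by hand) --------
tmm_oracle <- function(counts, logratio_trim = 0.3, abs_trim = 0.05) {
  counts <- as.matrix(counts) # samples x features
  lib <- rowSums(counts)
  f75 <- apply(counts, 1, function(x) quantile(x, 0.75)) / lib
  ref <- which.min(abs(f75 - mean(f75)))
  one_factor <- function(i) {
    y <- counts[i, ]; r <- counts[ref, ]
    keep <- y > 0 & r > 0
    y <- y[keep]; r <- r[keep]
    M <- log2((y / lib[i]) / (r / lib[ref]))
    A <- 0.5 * log2((y / lib[i]) * (r / lib[ref]))
    w <- (lib[i] - y) / (lib[i] * y) + (lib[ref] - r) / (lib[ref] * r)
    if (max(abs(M)) < 1e-6) return(1)
    n <- length(M)
    loM <- floor(n * logratio_trim) + 1; hiM <- n + 1 - loM
    loA <- floor(n * abs_trim) + 1; hiA <- n + 1 - loA
    rM <- rank(M); rA <- rank(A)
    k <- rM >= loM & rM <= hiM & rA >= loA & rA <= hiA
    2^(sum(M[k] / w[k]) / sum(1 / w[k]))
  }
  f <- vapply(seq_len(nrow(counts)), one_factor, numeric(1))
  f / exp(mean(log(f)))
}

# --- brute-force centralities on small graphs --------------------------------
# edges: 2-column matrix of 1-based node indices; n nodes. Enumerates all
# simple paths per pair to find shortest-path counts.
brute_centralities <- function(n, edges) {
  adj <- lapply(seq_len(n), function(v) integer(0))
  if (nrow(edges)) for (k in seq_len(nrow(edges))) {
    a <- edges[k, 1]; b <- edges[k, 2]
    adj[[a]] <- c(adj[[a]], b); adj[[b]] <- c(adj[[b]], a)
  }
  all_paths <- function(s, t) {
    res <- list()
    walk <- function(path) {
      v <- path[length(path)]
      if (v == t) { res[[length(res) + 1]] <<- path; return() }
      for (w in adj[[v]]) if (!(w %in% path)) walk(c(path, w))
    }
    walk(s)
    res
  }
  dist <- matrix(Inf, n, n); diag(dist) <- 0
  paths <- vector("list", n * n)
  for (s in seq_len(n)) for (t in seq_len(n)) if (s < t) {
    ps <- all_paths(s, t)
    if (length(ps)) {
      lens <- vapply(ps, length, integer(1)) - 1L
      d <- min(lens)
      dist[s, t] <- dist[t, s] <- d
      paths[[(s - 1) * n + t]] <- ps[lens == d]
    }
  }
  btw <- numeric(n)
  for (s in seq_len(n)) for (t in seq_len(n)) if (s < t && is.finite(dist[s, t])) {
    sp <- paths[[(s - 1) * n + t]]
    for (v in seq_len(n)) if (v != s && v != t) {
      through <- sum(vapply(sp, function(p) v %in% p, logical(1)))
      btw[v] <- btw[v] + through / length(sp)
    }
  }
  clo <- vapply(seq_len(n), function(v) {
    reach <- which(is.finite(dist[v, ]) & seq_len(n) != v)
    if (!length(reach)) return(0)
    comp_size <- length(reach) + 1
    (comp_size - 1) / sum(dist[v, reach])
  }, numeric(1))
  deg <- vapply(seq_len(n), function(v) length(adj[[v]]), numeric(1))
  list(degree = deg, betweenness = btw, closeness = clo)
}

# --- exact signed-rank two-sided p by full sign-pattern enumeration ----------
wilcox_enum_p <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  if (!n) return(1)
  r <- rank(abs(d))
  W_obs <- sum(r[d > 0])
  total <- sum(r)
  Ws <- vapply(0:(2^n - 1), function(mask) {
    sum(r[bitwAnd(bitwShiftR(mask, 0:(n - 1)), 1L) == 1L])
  }, numeric(1))
  lower <- mean(Ws <= W_obs + 1e-9)
  upper <- mean(Ws >= W_obs - 1e-9)
  min(1, 2 * min(lower, upper))
}

# --- weighted UniFrac by explicit per-branch accumulation --------------------
# Independent traversal: adjacency recursion from the root of an ape tree.
unifrac_brute <- function(p, q, tree, normalized = TRUE) {
  tips <- tree$tip.label
  pv <- setNames(numeric(length(tips)), tips); pv[names(p)] <- p
  qv <- setNames(numeric(length(tips)), tips); qv[names(q)] <- q
  pv <- pv / sum(pv); qv <- qv / sum(qv)
  ntip <- length(tips)
  root <- ntip + 1
  kids <- split(seq_len(nrow(tree$edge)), tree$edge[, 1])
  bl <- if (is.null(tree$edge.length)) rep(1, nrow(tree$edge)) else tree$edge.length
  num <- 0; den <- 0
  below <- function(node) { # returns c(massA, massB) under node
    if (node <= ntip) return(c(pv[node], qv[node]))
    tot <- c(0, 0)
    for (e in kids[[as.character(node)]]) {
      m <- below(tree$edge[e, 2])
      num <<- num + bl[e] * abs(m[1] - m[2])
      den <<- den + bl[e] * (m[1] + m[2])
      tot <- tot + m
    }
    tot
  }
  below(root)
  as.numeric(if (normalized) num / den else num)
}

# --- Benjamini-Hochberg step-up by hand --------------------------------------
bh_hand <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- numeric(m)
  run_min <- Inf
  for (k in m:1) {
    run_min <- min(run_min, p[o[k]] * m / k)
    adj[o[k]] <- min(1, run_min)
  }
  adj
}
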