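# SparCC, permutation p-values, deconvolution, RMT threshold, network
# construction, centralities, keystones, power-law fits.

test_that("SparCC: unit diagonal, planted correlation, type-I behaviour", {
  sim <- simulate_compositional_counts(100, 10, NULL, depth = 2e4, seed = 1)
  rho <- sparcc(sim$counts)
  expect_true(all(diag(rho) == 1))
  expect_equal(rho, t(rho), tolerance = 1e-9)
  expect_true(all(abs(rho) <= 1))
  # two taxa sharing a log-normal basis are strongly correlated
  pl <- simulate_compositional_counts(200, 8,
                                      data.frame(i = 1, j = 2, rho = 0.99),
                                      depth = 5e4, seed = 2)
  expect_gt(sparcc(pl$counts)[1, 2], 0.9)
  expect_error(sparcc(matrix(1, 10, 3)), "at least 4")
})

test_that("permutation p-values: lower bound, power, null uniformity", {
  pl <- simulate_compositional_counts(60, 6,
                                      data.frame(i = 1, j = 2, rho = 0.95),
                                      depth = 2e4, seed = 3)
  rho <- sparcc(pl$counts)
  p <- permutation_pvalues(pl$counts, rho, n_perm = 60, seed = 4)
  expect_true(all(p >= 1 / 61 - 1e-12))
  expect_equal(p[1, 2], 1 / 61) # planted pair sits at the lower bound
  # on independent data, p-values are approximately uniform
  nl <- simulate_compositional_counts(80, 35, NULL, depth = 2e4, seed = 5)
  rn <- sparcc(nl$counts)
  pn <- permutation_pvalues(nl$counts, rn, n_perm = 60, seed = 6)
  pv <- pn[upper.tri(pn)] # 595 pairs
  ks <- max(abs(ecdf(pv)(seq(0, 1, 0.01)) - seq(0, 1, 0.01)))
  expect_lt(ks, 0.1)
})

test_that("network deconvolution: fixed point, symmetry, transitive shrinkage,
           involution", {
  Z <- matrix(0, 4, 4)
  expect_equal(network_deconvolution(Z), Z, ignore_attr = TRUE)
  G <- diag(3)
  G[1, 2] <- G[2, 1] <- 0.8
  G[2, 3] <- G[3, 2] <- 0.8
  G[1, 3] <- G[3, 1] <- 0.64 # transitive product
  D <- network_deconvolution(G, zero_diag = FALSE)
  expect_equal(D, t(D), tolerance = 1e-9)
  expect_lt(abs(D[1, 3]), 0.64)
  # the direct A-B effect remains the dominant entry
  expect_gt(abs(D[1, 2]), abs(D[1, 3]))
  # involution: forward closure D(I-D)^{-1} recovers the scaled input
  s <- attr(D, "scale")
  back <- D %*% solve(diag(3) - D)
  expect_equal(back, s * G, tolerance = 1e-8)
})

test_that("RMT threshold stays in the grid and finds the noise/structure split", {
  # pure noise: qualifying threshold at the low end
  set.seed(11)
  X <- matrix(rnorm(300 * 25), 300)
  thr <- rmt_threshold(cor(X))
  expect_gte(as.numeric(thr), 0.30)
  expect_lt(as.numeric(thr), 0.5)
  # planted blocks (rho 0.9) over correlated noise (rho 0.2):
  # threshold falls strictly between noise and block levels
  res <- vapply(1:3, function(seed) {
    R <- matrix(0.2, 40, 40)
    for (b in 0:7) R[b * 5 + 1:5, b * 5 + 1:5] <- 0.9
    diag(R) <- 1
    set.seed(seed)
    Xb <- matrix(rnorm(200 * 40), 200) %*% chol(R)
    as.numeric(rmt_threshold(cor(Xb)))
  }, numeric(1))
  expect_true(all(res > 0.3 & res < 0.9))
  expect_error(rmt_threshold(diag(5)), "at least 20")
})

test_that("build_network enforces both cutoffs and partitions edge signs", {
  taxa <- paste0("t", 1:6)
  rho <- diag(6); dimnames(rho) <- list(taxa, taxa)
  p <- matrix(1, 6, 6, dimnames = list(taxa, taxa))
  rho[1, 2] <- rho[2, 1] <- 0.77; p[1, 2] <- p[2, 1] <- 1e-9 # rho too low
  rho[1, 3] <- rho[3, 1] <- 0.90; p[1, 3] <- p[3, 1] <- 0.01 # fdr too high
  rho[4, 5] <- rho[5, 4] <- 0.78; p[4, 5] <- p[5, 4] <- 1e-9 # keeps
  rho[4, 6] <- rho[6, 4] <- -0.95; p[4, 6] <- p[6, 4] <- 1e-9 # keeps, negative
  net <- build_network(rho, p)
  expect_equal(nrow(net$edges), 2)
  expect_false(any(net$edges$rho == 0.77))
  expect_false(any(net$edges$fdr > 0.001))
  expect_equal(sum(net$edges$sign == "positive") +
                 sum(net$edges$sign == "negative"), nrow(net$edges))
  expect_setequal(net$nodes$taxon, c("t4", "t5", "t6"))
})

test_that("centralities equal brute-force enumeration on random small graphs", {
  # path A-B-C: B carries the single shortest path
  g <- igraph::make_graph(~ A - B, B - C)
  ct <- centralities(g)
  expect_equal(ct$betweenness[ct$node == "B"], 1)
  expect_equal(ct$betweenness[ct$node == "A"], 0)
  # star: center degree n, isolated node zero degree and closeness
  st <- igraph::graph_from_literal(c - -x1, c - -x2, c - -x3, c - -x4, iso)
  cs <- centralities(st)
  expect_equal(cs$degree[cs$node == "c"], 4)
  expect_equal(cs$degree[cs$node == "iso"], 0)
  expect_equal(cs$closeness[cs$node == "iso"], 0)
  # 100 random graphs up to 8 nodes against the path-enumeration oracle
  set.seed(17)
  for (i in 1:100) {
    n <- sample(3:8, 1)
    pairs <- t(combn(n, 2))
    keep <- runif(nrow(pairs)) < 0.4
    edges <- pairs[keep, , drop = FALSE]
    g <- igraph::make_empty_graph(n, directed = FALSE)
    g <- igraph::add_edges(g, t(edges))
    igraph::V(g)$name <- paste0("v", seq_len(n))
    got <- centralities(g)
    want <- brute_centralities(n, edges)
    expect_equal(got$degree, want$degree)
    expect_equal(got$betweenness, want$betweenness, tolerance = 1e-9)
    expect_equal(got$closeness, want$closeness, tolerance = 1e-9)
  }
})

test_that("keystones are the intersection of both top-k lists", {
  tab <- data.frame(node = c("a", "b", "c", "d"),
                    degree = c(10, 9, 2, 1),
                    betweenness = c(50, 1, 40, 0),
                    closeness = 1)
  expect_equal(keystone_select(tab, k = 2), "a") # b top-degree only
  expect_setequal(keystone_select(tab, k = 10), tab$node) # k >= n: everyone
  # ties at rank k are all included
  tab2 <- data.frame(node = c("a", "b", "c"), degree = c(5, 5, 5),
                     betweenness = c(3, 3, 3), closeness = 1)
  expect_setequal(keystone_select(tab2, k = 1), c("a", "b", "c"))
})

test_that("power-law MLE recovers the exponent and flags degeneracy", {
  set.seed(19)
  x <- rpowerlaw(2000, 2.5)
  fit <- powerlaw_fit(x)
  expect_lt(abs(fit$alpha - 2.5), 0.3)
  expect_gt(fit$alpha, 1)
  # alpha stays above 1 for arbitrary data
  set.seed(20)
  y <- sample(1:5, 50, TRUE)
  expect_gt(powerlaw_fit(y)$alpha, 1)
  expect_true(powerlaw_fit(rep(3, 20))$degenerate)
})
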