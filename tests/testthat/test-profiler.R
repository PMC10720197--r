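# Abundance filtering, diversity metrics, UniFrac, rarefaction, TMM, Stokes.

test_that("depth filter, normalization and off-target pooling", {
  hits <- data.frame(gene = c("geneA", "geneB", "geneC"),
                     depth = c(30, 14, 30),
                     species = c("sp1", "sp2", "sp1"),
                     genus = c("g1", "g2", "g1"))
  p <- depth_profile_to_abundance(hits, min_depth = 15)
  expect_equal(unname(p$abundance["sp1"]), 1) # geneB filtered at depth 14
  expect_false("sp2" %in% names(p$abundance))
  # a hit at exactly the threshold survives
  hits$depth[2] <- 15
  p2 <- depth_profile_to_abundance(hits, min_depth = 15)
  expect_equal(unname(p2$abundance["sp2"]), 15 / 75)
  # plain normalization without filtering
  h3 <- data.frame(gene = c("a", "b"), depth = c(30, 10),
                   species = c("sp1", "sp2"), genus = c("g", "g"))
  p3 <- depth_profile_to_abundance(h3, min_depth = 0)
  expect_equal(unname(p3$abundance), c(0.75, 0.25))
  # off-target pooling preserves total mass 1
  h4 <- data.frame(gene = c("a", "b"), depth = c(80, 20),
                   species = c("sp1", "sp3"), genus = c("g", "g"))
  p4 <- depth_profile_to_abundance(h4, min_depth = 0, expected_taxa = "sp1")
  expect_equal(p4$off_target_mass, 0.2)
  expect_equal(sum(p4$abundance) + p4$off_target_mass, 1)
  expect_error(depth_profile_to_abundance(hits[hits$depth > 100, , drop = FALSE]),
               "no hits")
  expect_error(depth_profile_to_abundance(
    data.frame(gene = "a", depth = 3, species = "s", genus = "g"),
    min_depth = 15), "empty profile")
})

test_that("alpha diversity closed forms", {
  u <- alpha_diversity(c(5, 5, 5, 5))
  expect_equal(u$shannon, log(4))
  expect_equal(u$observed, 4)
  s <- alpha_diversity(c(0, 7, 0))
  expect_equal(s$shannon, 0); expect_equal(s$observed, 1)
  # S=5, f1=2, f2=1 -> chao1 = 5 + 4/2 = 7
  ch <- alpha_diversity(c(1, 1, 2, 3, 4))
  expect_equal(ch$chao1, 7)
  # bias-corrected form when no doubletons: S + f1(f1-1)/2
  ch2 <- alpha_diversity(c(1, 1, 3))
  expect_equal(ch2$chao1, 3 + 2 * 1 / 2)
  expect_warning(e <- alpha_diversity(c(0, 0)), "empty")
  expect_equal(e$observed, 0)
})

test_that("Bray-Curtis formula and edge cases", {
  expect_equal(bray_curtis(c(a = 1, b = 2), c(a = 1, b = 2)), 0)
  expect_equal(bray_curtis(c(a = 1), c(b = 3)), 1)
  expect_equal(bray_curtis(c(0.5, 0.5, 0), c(1, 0, 0)), 0.5)
  expect_error(bray_curtis(c(0, 0), c(0, 0)), "all-zero")
})

test_that("weighted UniFrac equals the brute-force branch sum", {
  lin <- data.frame(kingdom = "F",
                    genus = c("g1", "g1", "g2", "g3"),
                    species = c("s1", "s2", "s3", "s4"))
  tree <- lineage_tree(lin, add_off_target = FALSE)
  set.seed(77)
  for (i in 1:10) {
    p <- setNames(runif(4), c("s1", "s2", "s3", "s4")); p <- p / sum(p)
    q <- setNames(runif(4), c("s1", "s2", "s3", "s4")); q <- q / sum(q)
    expect_equal(weighted_unifrac(p, q, tree), unifrac_brute(p, q, tree),
                 tolerance = 1e-12)
    expect_equal(weighted_unifrac(p, q, tree), weighted_unifrac(q, p, tree))
    expect_equal(weighted_unifrac(p, q, tree, normalized = FALSE),
                 unifrac_brute(p, q, tree, normalized = FALSE),
                 tolerance = 1e-12)
  }
  expect_equal(weighted_unifrac(c(s1 = 1), c(s1 = 1), tree), 0)
  # star tree: normalized distance 1 for disjoint singletons, L1/2 in general
  star <- ape::read.tree(text = "(a:1,b:1,c:1);")
  expect_equal(weighted_unifrac(c(a = 1), c(b = 1), star), 1)
  for (i in 1:5) {
    p <- setNames(runif(3), c("a", "b", "c")); p <- p / sum(p)
    q <- setNames(runif(3), c("a", "b", "c")); q <- q / sum(q)
    expect_equal(weighted_unifrac(p, q, star, normalized = FALSE),
                 sum(abs(p - q)), tolerance = 1e-12)
    expect_equal(weighted_unifrac(p, q, star), sum(abs(p - q)) / 2,
                 tolerance = 1e-12)
  }
  expect_error(weighted_unifrac(c(zz = 1), c(a = 1), star), "zz")
})

test_that("off-target mass flows into the off_target leaf for distances", {
  lin <- data.frame(kingdom = "F", genus = c("g1", "g2"),
                    species = c("s1", "s2"))
  tree <- lineage_tree(lin)
  expect_true("off_target" %in% tree$tip.label)
  pr <- structure(list(level = "species", abundance = c(s1 = 0.8),
                       off_target_mass = 0.2), class = "abundance_profile")
  truth <- c(s1 = 1)
  expect_gt(weighted_unifrac(truth, pr, tree), 0)
})

test_that("rarefaction: endpoint, monotone expectation, singleton detection", {
  counts <- c(a = 500, b = 300, c = 150, d = 50)
  rc <- rarefaction_curve(counts, c(100, 400, 1000), n_reps = 20, seed = 3)
  expect_equal(rc$pct[3], 100)
  expect_true(all(diff(rc$richness) >= 0))
  expect_error(rarefaction_curve(counts, 2000), "exceeds")
  # a taxon with 1 read in N is detected with frequency ~ d/N
  counts2 <- c(common = 999, rare = 1)
  n_rep <- 400; d <- 300
  rc2 <- rarefaction_curve(counts2, d, n_reps = n_rep, seed = 4)
  det <- rc2$richness - 1 # detection frequency of the rare taxon
  pb <- qbinom(c(0.005, 0.995), n_rep, d / 1000) / n_rep
  expect_gte(det, pb[1]); expect_lte(det, pb[2])
})

test_that("TMM matches the brute-force oracle on 20-feature toys", {
  set.seed(99)
  for (i in 1:5) {
    a <- rpois(20, 200) + 1
    b <- a * 2
    b[1:4] <- rpois(4, 2000) # composition outliers
    cmat <- rbind(s1 = a, s2 = b, s3 = rpois(20, 300) + 1)
    got <- tmm_normalize(cmat)$factors
    want <- tmm_oracle(cmat)
    expect_equal(unname(got), unname(want), tolerance = 1e-8)
    expect_equal(exp(mean(log(got))), 1, tolerance = 1e-9)
  }
  # identical samples need no correction
  eq <- rbind(s1 = rpois(20, 100) + 1, s2 = 0)
  eq["s2", ] <- eq["s1", ]
  expect_equal(unname(tmm_normalize(eq)$factors), c(1, 1))
  # a pure library-size doubling leaves TMM factors at 1
  dbl <- rbind(s1 = rpois(20, 100) + 1, s2 = 0)
  dbl["s2", ] <- 2 * dbl["s1", ]
  expect_equal(unname(tmm_normalize(dbl)$factors), c(1, 1), tolerance = 1e-9)
})

test_that("enrichment folds are ratio-of-ratios", {
  r <- enrichment_ratio(fungal_enriched = c(20, 2), bacterial_enriched = c(100, 100),
                        fungal_control = c(1, 2), bacterial_control = c(100, 100))
  expect_equal(r$fold, c(20, 1))
  expect_equal(attr(r, "mean_fold"), 10.5)
  expect_error(enrichment_ratio(1, 0, 1, 1), "positive")
})

test_that("Stokes solver: inverse consistency, scaling law, degenerate density", {
  t1 <- stokes_solve(D = 4e-4, eta = 0.015, Rf = 11.4, Ro = 6.9,
                     rho_p = 1.1, rho_f = 1.005, omega = 2 * pi * 50)
  D_back <- stokes_solve(eta = 0.015, Rf = 11.4, Ro = 6.9, rho_p = 1.1,
                         rho_f = 1.005, omega = 2 * pi * 50, t = t1)
  expect_equal(unname(D_back), 4e-4, tolerance = 1e-9)
  # t scales as 1/omega^2
  t2 <- stokes_solve(D = 4e-4, eta = 0.015, Rf = 11.4, Ro = 6.9,
                     rho_p = 1.1, rho_f = 1.005, omega = 4 * pi * 50)
  expect_equal(unname(t1 / t2), 4, tolerance = 1e-12)
  expect_error(stokes_solve(D = 4e-4, eta = 0.015, Rf = 11.4, Ro = 6.9,
                            rho_p = 1, rho_f = 1, omega = 100),
               "sediment")
  expect_error(stokes_solve(eta = 0.015, Rf = 11.4, Ro = 6.9, rho_p = 1.1,
                            rho_f = 1.005, omega = 100, t = 10, D = 1e-4),
               "exactly one")
})

test_that("profiling converges to community truth with unambiguous references", {
  # error-free reads, min_depth 0: recovered abundances approach the truth
  set.seed(55)
  pool <- mock_species_pool(n_species = 8, n_genera = 5, seed = 13)
  comm <- sample_mock_community(pool, 6, seed = 14)
  pr <- profile_mock_community(comm, pool, n_reads = 1e5, error_rate = 0,
                               min_depth = 0, seed = 15)
  truth <- pr$truth$species
  est <- pr$shotgun$species$abundance[names(truth)]
  expect_lt(sum(abs(est - truth)), 0.05)
})
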