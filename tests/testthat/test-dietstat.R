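# Residual energy adjustment, ICC, exact signed-rank, association screens,
# longitudinal dynamics.

test_that("residual-method adjustment matches the hand OLS oracle", {
  d <- data.frame(energy = c(1, 2, 3), nutrient_1 = c(2, 4, 9))
  adj <- energy_adjust(d, "nutrient_1")
  # slope 3.5, intercept -2: residuals (0.5, -1, 0.5), mean 5
  expect_equal(adj$nutrient_1, c(5.5, 4, 5.5))
  # proportional nutrient collapses to its mean
  d2 <- data.frame(energy = c(10, 20, 30, 40), nutrient_1 = c(1, 2, 3, 4))
  expect_equal(energy_adjust(d2, "nutrient_1")$nutrient_1, rep(2.5, 4))
  # zero slope leaves values untouched
  d3 <- data.frame(energy = c(1, 2, 3, 4), nutrient_1 = c(5, 7, 7, 5))
  expect_equal(energy_adjust(d3, "nutrient_1")$nutrient_1, d3$nutrient_1)
  # invariance: shifting energy by a constant changes nothing
  d4 <- data.frame(energy = c(5, 9, 4, 7, 8), nutrient_1 = c(3, 8, 2, 6, 5))
  d5 <- d4; d5$energy <- d5$energy + 1000
  expect_equal(energy_adjust(d4, "nutrient_1")$nutrient_1,
               energy_adjust(d5, "nutrient_1")$nutrient_1)
  d6 <- data.frame(energy = rep(5, 4), nutrient_1 = 1:4)
  expect_warning(a6 <- energy_adjust(d6, "nutrient_1"), "constant")
  expect_equal(a6$nutrient_1, d6$nutrient_1)
})

test_that("ICC(2,1): perfect agreement, noise, sensitivity to shifts", {
  expect_equal(icc(1:10, 1:10)$icc, 1)
  # independent administrations: ICC stays near zero
  iccs <- vapply(1:20, function(s) {
    set.seed(s)
    icc(rnorm(50), rnorm(50))$icc
  }, numeric(1))
  expect_lt(median(abs(iccs)), 0.3)
  expect_lt(mean(abs(iccs)), 0.25)
  # a constant shift lowers absolute-agreement ICC but not consistency ICC
  x <- c(1, 3, 5, 7, 9)
  shifted <- icc(x, x + 2)$icc
  expect_lt(shifted, icc(x, x)$icc)
  expect_equal(icc(x, x + 2, type = "ICC3")$icc, 1)
  expect_error(icc(rep(1, 5), rep(1, 5)), "zero total variance")
})

test_that("exact signed-rank equals full sign-pattern enumeration for n <= 10", {
  # canonical example: n = 5, all differences positive -> p = 2/32
  expect_equal(wilcoxon_signed_exact(c(1, 2, 3, 4, 5))$p.value, 0.0625)
  set.seed(33)
  for (i in 1:40) {
    n <- sample(3:10, 1)
    d <- sample(-6:6, n, replace = TRUE) # includes zeros and ties
    got <- wilcoxon_signed_exact(d)
    want <- wilcox_enum_p(d)
    expect_equal(got$p.value, want, tolerance = 1e-12,
                 label = paste("diffs:", paste(d, collapse = ",")))
  }
  # identical vectors degenerate to p = 1 with a flag
  w0 <- wilcoxon_signed_exact(c(2, 2, 2), c(2, 2, 2))
  expect_equal(w0$p.value, 1)
  expect_true(w0$degenerate)
})

test_that("reproducibility over two administrations", {
  d <- simulate_diet_profiles(8, 2, noise_sd = 0.05, seed = 7)
  t1 <- d[d$timepoint == 1, ]; t2 <- d[d$timepoint == 2, ]
  rt <- reproducibility_test(t1, t2)
  expect_true(all(c("wilcoxon_p", "icc") %in% names(rt)))
  expect_true(all(rt$wilcoxon_p >= 0 & rt$wilcoxon_p <= 1))
  # zero-noise administrations are flagged degenerate with high ICC
  d0 <- simulate_diet_profiles(8, 2, noise_sd = 0, seed = 8)
  rt0 <- reproducibility_test(d0[d0$timepoint == 1, ], d0[d0$timepoint == 2, ])
  expect_true(all(rt0$wilcoxon_p == 1))
  expect_true(all(rt0$degenerate))
})

test_that("association screen: exact correlations, joint BH, invariances", {
  set.seed(41)
  n <- 30
  x <- rnorm(n)
  feats <- data.frame(f_same = x, f_noise = rnorm(n),
                      row.names = paste0("s", 1:n))
  diet <- data.frame(v_same = x, v_inv = -x, v_other = rnorm(n),
                     row.names = paste0("s", 1:n))
  scr <- association_screen(feats, diet)
  expect_equal(scr$rho[scr$feature == "f_same" & scr$variable == "v_same"], 1)
  expect_equal(scr$rho[scr$feature == "f_same" & scr$variable == "v_inv"], -1)
  # joint BH equals the hand step-up computation
  expect_equal(scr$fdr, bh_hand(scr$p))
  expect_true(all(diff(scr$fdr[order(scr$p)]) >= -1e-12))
  # Spearman is invariant under monotone transforms
  scr2 <- association_screen(exp(feats), diet)
  expect_equal(scr2$rho, scr$rho)
  # perfect inverse ranks on a 4-point toy
  f3 <- data.frame(f = c(1, 2, 3, 4), row.names = paste0("s", 1:4))
  d3 <- data.frame(v = c(4, 3, 2, 1), row.names = paste0("s", 1:4))
  expect_equal(association_screen(f3, d3)$rho, -1)
  expect_error(association_screen(
    data.frame(a = 1:3, row.names = c("x", "y", "z")),
    data.frame(b = 1:3, row.names = c("q", "r", "s"))), "overlap")
  expect_message(association_screen(
    cbind(feats, konst = 1), diet), "constant")
})

test_that("dynamics: intra/inter labelling and community comparison", {
  # two subjects with distinct constant profiles: intra 0, inter > 0
  prof <- rbind(c(1, 0), c(1, 0), c(0, 1), c(0, 1))
  dyn <- dynamics_analysis(prof, subject = c("a", "a", "b", "b"),
                           timepoint = c(1, 2, 1, 2))
  dd <- dyn$dissimilarities
  expect_true(all(dd$value[dd$type == "intra"] == 0))
  expect_true(all(dd$value[dd$type == "inter"] == 1))
  # all-identical profiles: everything zero, degenerate
  same <- matrix(rep(c(0.5, 0.5), 4), 4, byrow = TRUE)
  dyn0 <- dynamics_analysis(same, c("a", "a", "b", "b"), c(1, 2, 1, 2))
  expect_true(all(dyn0$dissimilarities$value == 0))
  expect_true(dyn0$degenerate)
  # a community with 3x the temporal noise shows higher dynamics (paired)
  set.seed(51)
  n_sub <- 6; n_tp <- 8; n_tax <- 25
  base <- matrix(rexp(n_sub * n_tax), n_sub)
  base <- base / rowSums(base)
  mk <- function(noise) {
    m <- do.call(rbind, lapply(seq_len(n_sub), function(s)
      t(vapply(seq_len(n_tp), function(tp) {
        v <- base[s, ] * exp(noise * rnorm(n_tax))
        v / sum(v)
      }, numeric(n_tax)))))
    m
  }
  fungal <- mk(0.9); bacterial <- mk(0.3)
  subject <- rep(seq_len(n_sub), each = n_tp)
  timepoint <- rep(seq_len(n_tp), n_sub)
  dyn2 <- dynamics_analysis(fungal, subject, timepoint, bacterial)
  expect_gt(dyn2$community_comparison$mean_diff, 0)
  expect_lt(dyn2$community_comparison$p.value, 0.01)
  # a subject with a single timepoint is excluded from the intra set
  expect_warning(dynamics_analysis(prof[1:3, ], c("a", "a", "b"), c(1, 2, 1)),
                 "single timepoint")
})
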