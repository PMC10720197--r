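# Synthetic generators: construction truth, determinism, sampling laws.

test_that("genome synthesis plants the requested arrays with exact truth", {
  tpl <- short_templates()
  spec <- genome_spec(8000, data.frame(contig = 1, start = 1000, copies = 5,
                                       spacer = 120),
                      its_length = 500, flank_divergence = 0,
                      templates = tpl, seed = 3)
  g <- synthesize_genome(spec)
  expect_equal(g$truth$copy_number, 5)
  expect_equal(nrow(g$truth$loci), 5)
  # zero divergence: exact string search finds exactly K LSU occurrences
  hits <- gregexpr(tpl$lsu, g$contigs[[1]], fixed = TRUE)[[1]]
  expect_equal(length(hits[hits > 0]), 5)
  # each planted flank equals its template exactly
  l1 <- g$truth$loci[1, ]
  expect_equal(substr(g$contigs[[1]], l1$start - nchar(tpl$lsu) + 1, l1$start),
               tpl$lsu)
  expect_equal(substr(g$contigs[[1]], l1$end + 1, l1$end + nchar(tpl$ssu)),
               tpl$ssu)
})

test_that("truncate_last_copy removes the trailing SSU flank and flags the locus", {
  tpl <- short_templates()
  spec <- genome_spec(9000, data.frame(contig = 1, start = 1000, copies = 3,
                                       spacer = 120),
                      its_length = 500, flank_divergence = 0, templates = tpl,
                      truncate_last_copy = TRUE, seed = 5)
  g <- synthesize_genome(spec)
  expect_equal(sum(g$truth$loci$flag == "end_truncated"), 1)
  expect_equal(g$truth$copy_number, 3)
  # the truncated copy's SSU flank is absent: only 2 SSU template occurrences
  hits <- gregexpr(tpl$ssu, g$contigs[[1]], fixed = TRUE)[[1]]
  expect_equal(length(hits[hits > 0]), 2)
  # contig now ends mid-ITS of the last copy
  expect_equal(nchar(g$contigs[[1]]), max(g$truth$loci$end))
})

test_that("overlapping or out-of-bounds arrays are rejected", {
  tpl <- short_templates()
  expect_error(synthesize_genome(
    genome_spec(3000, data.frame(contig = 1, start = 2500, copies = 2,
                                 spacer = 100), templates = tpl)),
    "bounds")
  expect_error(synthesize_genome(
    genome_spec(20000, data.frame(contig = 1, start = c(1000, 1200),
                                  copies = 1, spacer = 100),
                its_length = 500, templates = tpl)),
    "overlap")
})

test_that("identical seeds give identical genomes and reads", {
  tpl <- short_templates()
  spec <- genome_spec(6000, data.frame(contig = 1, start = 500, copies = 2,
                                       spacer = 100), its_length = 450,
                      templates = tpl, n_markers = 2, seed = 77)
  g1 <- synthesize_genome(spec); g2 <- synthesize_genome(spec)
  expect_identical(g1$contigs, g2$contigs)
  r1 <- simulate_shotgun_reads(g1, 500, 80, 0.01, seed = 9)
  r2 <- simulate_shotgun_reads(g1, 500, 80, 0.01, seed = 9)
  expect_identical(r1, r2)
  # FASTA/FASTQ round trips preserve sequences and qualities
  fa <- tempfile(fileext = ".fasta"); fq <- tempfile(fileext = ".fastq")
  write_fasta(g1$contigs, fa)
  expect_equal(read_fasta(fa), g1$contigs)
  write_fastq(r1, fq)
  back <- read_fastq(fq)
  expect_equal(back$seq, r1$seq)
  expect_equal(back$id, r1$id)
  expect_true(all(back$qual == strrep("I", 80)))
})

test_that("shotgun reads: counts, purity at zero error, coverage law", {
  set.seed(1)
  contig <- c(ctg = paste(sample(c("A", "C", "G", "T"), 20000, TRUE),
                          collapse = ""))
  reads <- simulate_shotgun_reads(contig, 1000, 100, error_rate = 0,
                                  seed = 2)
  expect_equal(nrow(reads), 1000)
  # error-free reads are exact substrings of the contig or its revcomp
  fwd <- reads$src_strand == "+"
  expect_true(all(vapply(which(fwd)[1:50], function(i)
    grepl(reads$seq[i], contig, fixed = TRUE), logical(1))))
  expect_true(all(vapply(which(!fwd)[1:50], function(i)
    grepl(revcomp(reads$seq[i]), contig, fixed = TRUE), logical(1))))
  # depth at a fixed position over 20 seeds matches Poisson coverage nL/G
  G <- 20000; L <- 100; n <- 1000
  lambda <- n * L / G
  pos <- 10000
  cover <- vapply(1:20, function(s) {
    r <- simulate_shotgun_reads(contig, n, L, 0, seed = 100 + s)
    sum(r$src_pos <= pos & r$src_pos + L > pos)
  }, numeric(1))
  expect_lt(abs(mean(cover) - lambda), 3 * sqrt(lambda / 20))
})

test_that("amplicon sampling weight is abundance x copy number", {
  set.seed(8)
  its <- c(a = paste(sample(c("A", "C", "G", "T"), 500, TRUE), collapse = ""),
           b = paste(sample(c("A", "C", "G", "T"), 500, TRUE), collapse = ""))
  comm <- structure(list(members = data.frame(
    taxon = c("a", "b"), genus = c("ga", "gb"),
    abundance = c(0.5, 0.5), cn = c(10, 1))), class = "mock_community")
  n <- 5000
  reads <- simulate_its_amplicons(comm, its, n, 100, 0, seed = 4)
  ka <- sum(reads$src == "a")
  bounds <- qbinom(c(0.005, 0.995), n, 10 / 11)
  expect_gte(ka, bounds[1]); expect_lte(ka, bounds[2])
  # equal copy numbers reduce to plain abundances
  comm$members$cn <- c(3, 3)
  r2 <- simulate_its_amplicons(comm, its, n, 100, 0, seed = 5)
  k2 <- sum(r2$src == "a")
  b2 <- qbinom(c(0.005, 0.995), n, 0.5)
  expect_gte(k2, b2[1]); expect_lte(k2, b2[2])
  # single member takes every read; missing ITS is a named error
  comm$members <- comm$members[1, ]
  expect_true(all(simulate_its_amplicons(comm, its, 200, 100, 0)$src == "a"))
  expect_error(simulate_its_amplicons(comm, its["b"], 10, 100, 0), "a")
})

test_that("compositional counts close to the requested depth and correlations", {
  sim <- simulate_compositional_counts(40, 8, NULL, depth = 2000, seed = 6)
  expect_true(all(rowSums(sim$counts) == 2000))
  expect_equal(sim$basis_corr, diag(8))
  expect_error(simulate_compositional_counts(
    10, 4, matrix(c(1, 2, 2, 1, rep(0, 12)), 4), depth = 100),
    "positive-definite")
  # identity basis: log-basis sample correlations stay near zero
  meds <- vapply(1:20, function(s) {
    x <- simulate_compositional_counts(200, 6, NULL, depth = 1000, seed = s)
    cc <- cor(x$log_basis)
    median(abs(cc[upper.tri(cc)]))
  }, numeric(1))
  expect_true(all(meds < 0.2))
  # planted pair 0.9 is recovered in the log-basis
  pl <- simulate_compositional_counts(200, 6,
                                      data.frame(i = 1, j = 2, rho = 0.9),
                                      depth = 1000, seed = 3)
  expect_gt(cor(pl$log_basis[, 1], pl$log_basis[, 2]), 0.7)
})

test_that("diet tables have the questionnaire design shape", {
  d <- simulate_diet_profiles(6, 2, n_nutrients = 4, seed = 2)
  expect_equal(nrow(d), 12) # 6 subjects x 2 administrations
  expect_equal(sum(grepl("^nutrient_", names(d))), 4)
  expect_true("energy" %in% names(d))
  expect_false(any(duplicated(d[c("subject", "timepoint")])))
  # zero noise: both administrations identical per subject
  d0 <- simulate_diet_profiles(5, 2, noise_sd = 0, seed = 3)
  t1 <- d0[d0$timepoint == 1, -2]; t2 <- d0[d0$timepoint == 2, -2]
  rownames(t1) <- rownames(t2) <- NULL
  expect_equal(t1, t2)
  # energy correlates with the nutrient columns by construction
  dd <- simulate_diet_profiles(40, 1, noise_sd = 0.05, seed = 4)
  expect_gt(cor(dd$energy, dd$nutrient_1), 0.5)
})
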