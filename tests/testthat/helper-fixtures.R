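# Shared fixtures built in code at test time. Module tests use short flank
# templates so scans stay fast; the acceptance suite uses the full-length
# defaults.

# short flank templates + profiles for fast scanning tests
short_templates <- function() {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(90210)
  list(lsu = paste(sample(c("A", "C", "G", "T"), 80, TRUE), collapse = ""),
       ssu = paste(sample(c("A", "C", "G", "T"), 60, TRUE), collapse = ""))
}

short_profiles <- function(divergence = 0.02) {
  tpl <- short_templates()
  set.seed(311)
  aln_l <- vapply(1:8, function(i) mycometer:::.mutate_seq(tpl$lsu, divergence), "")
  aln_s <- vapply(1:8, function(i) mycometer:::.mutate_seq(tpl$ssu, divergence), "")
  list(lsu = build_profile(aln_l, "LSU"), ssu = build_profile(aln_s, "SSU"),
       templates = tpl)
}

# cache profiles + calibrations across tests within a file
.fixture_env <- new.env()
get_short_setup <- function() {
  if (is.null(.fixture_env$setup)) {
    pr <- short_profiles()
    .fixture_env$setup <- list(
      profiles = pr,
      cal_lsu = calibrate_profile(pr$lsu, NULL, seed = 11),
      cal_ssu = calibrate_profile(pr$ssu, NULL, seed = 12))
  }
  .fixture_env$setup
}

# full-length profiles (588/142) for the acceptance suite
get_full_setup <- function() {
  if (is.null(.fixture_env$full)) {
    tpl <- flank_templates()
    set.seed(6021)
    aln_l <- vapply(1:10, function(i) mycometer:::.mutate_seq(tpl$lsu, 0.02), "")
    aln_s <- vapply(1:10, function(i) mycometer:::.mutate_seq(tpl$ssu, 0.02), "")
    pl <- build_profile(aln_l, "LSU")
    ps <- build_profile(aln_s, "SSU")
    .fixture_env$full <- list(
      templates = tpl, lsu = pl, ssu = ps,
      cal_lsu = calibrate_profile(pl, NULL, seed = 21),
      cal_ssu = calibrate_profile(ps, NULL, seed = 22))
  }
  .fixture_env$full
}

# best local Viterbi cell score straight from the compiled scanner
viterbi_scan_cpp_wrap <- function(seqi, tab) {
  mycometer:::viterbi_scan_cpp(as.integer(seqi), tab$msc, tab$tr, tab$begin,
                               1e9)$max_score
}

# a tiny profile (few match states) for enumeration-oracle tests
tiny_profile <- function(M = 3, seed = 4) {
  set.seed(seed)
  aln <- vapply(1:4, function(i)
    paste(sample(c("A", "C", "G", "T"), M, TRUE), collapse = ""), "")
  build_profile(aln, "tiny")
}
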