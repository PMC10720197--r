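---
title: "Methods and design of mycometer"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design of mycometer}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`mycometer` estimates fungal rDNA ITS copy numbers, benchmarks ITS-amplicon
against shotgun mycobiome profiling on mock communities, and provides the
community ecology and diet statistics used downstream of such profiling.
This vignette explains the models, the tunable parameters, the synthetic
data the test suite runs on, and the design decisions taken where the
methodology admitted more than one reasonable choice.

## The copy-number problem

The ITS region is the universal fungal barcode, but it lies inside the rDNA
tandem array, which is present in tens to hundreds of copies per genome and
varies between strains of one species. Amplicon read counts therefore
measure abundance x copy number, not abundance. Two estimators quantify the
copy number:

* **CN-HMM** counts ITS loci directly in a genome assembly. It is exact
  when the assembly is complete, but short-read assemblers collapse tandem
  repeats, so on real assemblies it undercounts (often to one or two
  copies). It remains the method of choice for *extracting* the ITS
  sequence itself.
* **CN-MD** avoids the assembly by comparing mapping depths: reads are
  mapped to the ITS sequence and to single-copy marker genes; the ratio of
  the ITS depth to the median marker depth is the copy number, because one
  genome-equivalent of coverage passes through each single-copy gene once
  but through the ITS once per copy.

## CN-HMM

### Profile HMMs of the rRNA flanks

The conserved edges of the rRNA genes flanking the ITS anchor its
detection. `build_profile()` estimates, from a multiple alignment of flank
sequences, a nucleotide profile HMM: match columns are alignment columns
with under 50% gaps; match emissions are `(count + 1) / (n + 4)`
pseudocounted base frequencies; per-position match/insert/delete
transitions get the same +1 pseudocounting. With the +1 pseudocount a
column that is identical in an alignment of ten sequences has modal
emission 11/14 ≈ 0.79 — pseudocounts keep the model permissive at the
alignment depths typical for curated flank sets.

Scanning (`scan_sequence()`) is local Viterbi alignment in log2-odds space
against both strands: the alignment may enter at any match state (uniform
entry cost `-log2(M)`) and leave from any match state, so flanks truncated
by contig ends still score. Insert emissions equal the background, making
inserted bases score zero. Per strand, overlapping candidate alignments are
resolved greedily by score.

### E-values

Scores are converted to E-values by the Gumbel form `E = K N 2^-S` with the
decay fixed at `ln 2` (scores are bits) and `K` estimated by maximum
likelihood from the top scores of scans of dinucleotide-shuffled copies of
the target (`calibrate_profile()`; the shuffle permutes non-overlapping
2-mers, preserving dinucleotide composition up to chunk junctions). The
contractual part is the filter semantics — hits with `E > 0.001` are
discarded — not the constant itself, which is an empirical calibration; on
random sequence the expected false-positive count is approximately `e_max`
per scan, which the test suite checks. Calibration costs a few extra scans,
so a calibration computed once can be passed to `scan_sequence()` when
processing many genomes with one profile.

### Pairing rules

`count_copies()` pairs each LSU-flank hit with the nearest downstream
(strand-aware) unused SSU-flank hit whose inner-edge gap lies within
`[min_gap, max_gap]` = [400, 800] bp — the inner gap *is* the ITS length,
which is how the biological length range enters; boundaries are inclusive,
so gaps of 399 or 801 bp count nothing. Equidistant partner ties resolve by
bit score, making the procedure deterministic. An unpaired hit still counts
one copy when the window where its partner would sit extends past the
contig boundary (within `end_window`, default `max_gap`, of the end on the
appropriate side); such loci are flagged `end_truncated` and excluded from
FASTA extraction. Both hits of a pair must lie on the same strand — the
rDNA cistron is transcribed as one unit, so flanks of one copy cannot
disagree in orientation. Overlapping LSU/SSU hits are discarded pairwise
with a warning rather than guessed at.

Coordinates are 0-based half-open everywhere, including the BED output,
which uses the same convention natively.

## CN-MD

The depth pipeline filters alignment records below MAPQ 30 (ambiguously
placed reads carry MAPQ 0 from the internal aligner and are removed by this
filter), accumulates per-base depth over the aligned reference span, trims
50 bp from each gene end before averaging — read-edge positions are
systematically under-covered because a read must fit entirely inside the
reference — and takes the ITS-to-median-marker depth ratio. The mean depth
per usable base is itself the per-length normalisation; dividing again by
gene length would give the ratio units of 1/length and break the
interpretation as a copy number, so that reading was rejected. The median
across markers (not the mean) is used because single outlier markers with
inflated depth otherwise bias the denominator.

The internal aligner (`align_reads_minimal()`) is deliberately minimal:
exact seeds at three read offsets per strand, full-length ungapped
extension, unique-best placement at MAPQ 42, ties at MAPQ 0. It exists so
the pipeline and its tests need no external mapper; externally produced SAM
(including soft-clipped records, whose reference span is derived from the
CIGAR) is ingested by `read_sam()`.

## Mock-community benchmarking

`mock_species_pool()` builds a pool of 27 species across 14 genera, each
with a small single-contig genome (two species-specific 1 kb marker genes
plus one rDNA copy) and a nominal ITS copy number drawn uniformly from
11–137, the intraspecific range observed for *Candida albicans*-like and
*Saccharomyces cerevisiae*-like strains. The genome carries a *single*
physical rDNA copy while the nominal copy number weights the amplicon
simulator. That is deliberate: real short-read assemblies carry collapsed
arrays, and amplicon simulation from CN-replicated ITS sequences is exactly
how the bias propagates in practice; keeping genomes small also keeps
marker depths above the filter at benchmark read counts.

Per community, member abundances are uniform weights normalised to one;
shotgun reads are allocated proportionally to abundance x genome length,
amplicon reads proportionally to abundance x copy number. Both read sets
pass the same pipeline: map (markers vs pool-wide ITS database), trim-mean
depth, drop hits under 15x mean depth (the off-target filter), normalise
depths to abundances, pool taxa outside the community into an `off_target`
mass. Truth-vs-recovered distances use normalized weighted UniFrac on a
rank-lineage tree (kingdom → genus → species) with unit branch lengths; the
tree is shared between methods, so the ITS-vs-shotgun contrast is
insensitive to this tree choice, and the off-target mass hangs as a single
tip under the root so profiles stay normalised without invented lineages.
The depth filter applies to both sequencing modes alike.

## Network inference

`sparcc()` implements compositional correlation from log-ratio variances:
pseudocounted fractions, variation matrix `T_ij = var(log(x_i/x_j))`, basis
variances from the standard linear system, correlations from the basis
solution, with iterative exclusion of the single strongest pair above 0.1
per round (up to 10 rounds). The point estimate is deterministic; Dirichlet
resampling of the fractions is available behind a flag. Permutation
p-values shuffle each taxon independently and use the add-one estimator, so
they are bounded below by `1/(n_perm+1)`.

`network_deconvolution()` removes transitively induced correlations by the
spectral closure inverse: scale the observed matrix so its largest absolute
eigenvalue is 0.99, map each eigenvalue `λ → λ/(1+λ)`, reassemble. The
forward closure `D(I−D)^{-1}` recovers the scaled input exactly, which the
tests verify as a matrix identity.

`rmt_threshold()` selects the correlation cutoff at which the
nearest-neighbour spacing distribution of the unfolded eigenvalues turns
Poisson (random structure removed). Numerical choices: spline unfolding of
the cumulative spectral density; eigenvalue degeneracy removed by
collapsing values closer than 1% of the spectral range (dense modules
produce tight eigenvalue clusters that carry no spacing information and
would otherwise read as level repulsion); chi-square against the
exponential form over 20 bins, accepted at p > 0.05; and the reported
threshold is the smallest grid value that stays Poisson-consistent for five
consecutive grid steps. Persistence is checked over a short window rather
than the whole remaining grid because thresholds high enough to cut *into*
genuine modules re-create random-looking spacings — under a whole-grid rule
the estimate overshoots to the top of the grid and becomes seed-sensitive.
A spectrum left too degenerate to test counts as Poisson-consistent.

The pipeline order is SparCC → deconvolution → RMT threshold → FDR filter.
`build_network()` applies both cutoffs — `|rho| ≥ 0.78` (the
RMT-derived default) *and* BH-FDR ≤ 0.001, with BH computed jointly over
all unique pairs — and records edge signs. Centralities are unnormalized
shortest-path betweenness (raw path counts, the scale on which published
keystone tables report values), degree, and within-component closeness
`(n_c−1)/Σd`. Keystones are the intersection of the top-20 lists by degree
and by betweenness, ties at rank 20 included, ordered deterministically.
The power-law fit is the discrete maximum-likelihood exponent at fixed
`xmin` via the generalized zeta function, with a KS statistic against the
fitted law; constant degree sequences are flagged degenerate rather than
fitted.

## Diet statistics

Nutrient intakes are energy-adjusted by the residual method: OLS of each
nutrient on total energy, adjusted value = residual + nutrient mean. The
adjustment is invariant to shifting energy by a constant, and constant
energy degrades gracefully to the identity with a warning.
Questionnaire reproducibility uses ICC(2,1) — two-way random effects,
absolute agreement, single measure — because a systematic shift between
administrations should lower the score; the consistency form ICC(3,1) is
available behind a flag. The paired Wilcoxon test uses the exact signed-rank
distribution computed by a subset-sum recursion over doubled midranks, so
ties are handled exactly; the test equals full sign-pattern enumeration for
every n ≤ 10 (verified in the suite) and switches to the tie-corrected
normal approximation above n = 25. All-zero differences return p = 1 with a
degenerate flag. Association screens are Spearman correlations with BH
adjustment over the entire screen; an optional partial mode residualizes
both sides on user-supplied covariates first, since which covariates to
condition on is a study-level decision. Longitudinal dynamics label all
pairwise Bray–Curtis dissimilarities intra- or inter-individual, build
per-subject baseline trajectories, and compare communities by the paired
signed-rank test across matched subject-timepoints.

## What the simulators do and do not emulate

The generators reproduce the *structure* of the real inputs — tandem
arrays with known copy number and divergent flank copies, truncated
terminal copies, uniform-coverage single-end reads with i.i.d. substitution
errors and constant quality strings, amplicon sampling weighted by
abundance x CN, log-normal compositional bases closed by multinomial
sampling, subject-baseline diet tables — and are byte-reproducible per
seed. They do not emulate platform error profiles, indels (off by default
so truth coordinates stay exact), PCR chimeras, GC bias, paired-end
structure (which adds nothing to the tested arithmetic), or real taxonomic
annotation ambiguity. Passing tests therefore demonstrate correctness of
the estimators and statistics under their stated models, not robustness to
every artefact of real sequencing.

## Problem sizes

The suite exercises CN-HMM on 100 genomes with copy numbers in
{1, 2, 5, 20, 60, 150} at flank divergence up to 5%, CN-MD on 30 genomes
spanning 7–170 copies at 30x coverage, and the method comparison on ten
replicates of five communities with 50,000 reads per mode — sizes chosen so
the full suite runs in minutes on one core while keeping every estimate's
sampling error well inside the asserted tolerances. `scripts/acceptance.R`
re-runs the same analyses at reduced replication and records the problem
size alongside every value.

## Known limitations

* CN-HMM inherits assembly quality: collapsed arrays undercount, and the
  estimator cannot see copies the assembler never wrote.
* The E-value constant is calibrated per profile on shuffled sequence;
  absolute E-values are approximate (only the cutoff semantics are
  contractual).
* The internal aligner is ungapped and exact-seeded; it is a test-scale
  stand-in, not a replacement for a production mapper on real data.
* SparCC's basis solution assumes correlations are sparse; dense strong
  correlation structures violate the approximation, which the iterative
  exclusion only partially repairs.
* The RMT threshold depends on procedural choices (unfolding, binning,
  persistence) that the literature leaves open; the defaults here are
  declared, tested for stability, and documented above.
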