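# mycometer

Quantitative tools for profiling the fungal fraction of shotgun metagenomes
(the *mycobiome*), built around one biological fact: the fungal ITS region —
the standard fungal barcode — sits in the rDNA tandem array, whose copy
number varies enormously between strains (tens to hundreds of copies).
Amplicon counts therefore confound abundance with copy number, while shotgun
reads annotated against single-copy marker genes do not. `mycometer`
implements the two copy-number estimators, the in-silico benchmarking that
demonstrates the amplicon bias, and the downstream community statistics, all
runnable end to end on synthetic data.

## What the package computes

**CN-HMM — copy number from an assembly.** Profile HMMs of the rRNA flanks
on either side of the ITS (an LSU-side model of 588 match states and an
SSU-side model of 142) are scanned against both strands of every contig by
local Viterbi alignment. Hits with E-value above 0.001 are discarded
(`E = K · N · 2^-S`, with `K` calibrated on dinucleotide-shuffled sequence).
Flank hits are paired when the inner gap — the ITS length — lies in
[400, 800] bp (the biological range; 550 bp is typical), and an unpaired
flank whose partner window runs off the contig end still counts one
(end-truncated) copy. The copy number is the number of accepted loci.

**CN-MD — copy number from reads.** Reads are mapped to the genome's ITS
sequence and its single-copy marker genes; records below MAPQ 30 are
dropped; per-gene depth is averaged after trimming 50 bp from each gene end
(read-edge deflation); then

```
CN-MD = ITS trimmed-mean depth / median(marker trimmed-mean depths)
```

with the median guarding against outlier markers.

**Mock-community benchmarking.** Synthetic communities with known
composition are sequenced in silico two ways: shotgun reads from the member
genomes, and ITS amplicons drawn with weight `abundance × CN` (the amplicon
bias). Both read sets pass the same depth pipeline (mean-depth-below-15
filter, depth-proportional abundances, off-target pooling), and each
recovered profile is compared to the truth by normalized weighted UniFrac
on a shared rank-lineage tree.

**Ecology and diet statistics.** SparCC compositional correlation (log-ratio
variation matrix, basis-variance solve, iterative exclusion), permutation
p-values, network deconvolution (`λ → λ/(1+λ)` on the scaled spectrum),
random-matrix-theory thresholding of the correlation matrix (nearest-
neighbour eigenvalue spacings vs the Poisson form), graph construction at
`|rho| ≥ 0.78` and BH-FDR ≤ 0.001, degree/betweenness/closeness
centralities, keystone selection (intersection of both top-20 lists),
discrete power-law fits of degree sequences, alpha diversity
(observed/Shannon/Chao1), Bray–Curtis, rarefaction, TMM normalization,
energy adjustment of nutrient intakes by the residual method, ICC(2,1) and
exact signed-rank reproducibility tests, Spearman+BH association screens,
and longitudinal dissimilarity dynamics. A Stokes' law calculator
(`D = (18η·ln(Rf/Ro) / ((ρp−ρf)·ω²·t))^0.5`) supports planning the
centrifugation that separates fungal from bacterial cells.

Everything the pipelines consume can be generated by the built-in
simulators (genomes with planted rDNA arrays and ground truth, reads,
amplicons, compositional counts with known basis correlations, diet
tables), so the whole toolkit is testable without downloads.

## Worked example

```r
library(mycometer)

## profile HMMs for the two ITS flanks
tpl <- flank_templates()   # 588 bp LSU-side / 142 bp SSU-side templates
lsu <- build_profile(simulate_alignment(tpl$lsu, 10, 0.02, seed = 1), "LSU")
ssu <- build_profile(simulate_alignment(tpl$ssu, 10, 0.02, seed = 2), "SSU")

## a genome with a known 5-copy rDNA array and 6 single-copy markers
spec <- genome_spec(
  contig_lengths = 26000,
  arrays = data.frame(contig = 1, start = 3000, copies = 5, spacer = 300),
  flank_divergence = 0.03, n_markers = 6, marker_length = 1000, seed = 42)
genome <- synthesize_genome(spec)

## CN-HMM: scan, pair, count
res <- cn_hmm(genome, lsu, ssu)
res
#> CN-HMM result for genome: copy number 5 (5 paired, 0 end-truncated)
head(res$loci, 3)
#>    contig start  end strand completeness
#> 1 contig1  3588 4140      +       paired
#> 2 contig1  5168 5718      +       paired
#> 3 contig1  6748 7298      +       paired

## CN-MD: ~30x simulated shotgun coverage through the depth pipeline
reads <- simulate_shotgun_reads(genome, n_reads = 8000, seed = 7)
cn_md_pipeline(reads, c(ITS = unname(genome$its_seqs[1])), genome$marker_seqs)
#> CN-MD for genome: ITS depth 141.32 / marker median 30.51 = 4.63
```

The paired loci sit exactly at the planted coordinates and CN-HMM returns
the planted copy number; the CN-MD ratio recovers it to within sampling
noise of the 30x coverage (4.63 vs 5).

The amplicon bias, in two mock communities of 10–14 species with copy
numbers drawn from 11–137 and 50,000 reads per sequencing mode:

```r
pool <- mock_species_pool(seed = 1)
cmp  <- compare_profiling_methods(pool, n_communities = 2, n_reads = 5e4, seed = 3)
round(cmp[-1], 3)
#>   unifrac_its_species unifrac_shotgun_species unifrac_its_genus unifrac_shotgun_genus
#> 1               0.091                   0.009             0.068                 0.006
#> 2               0.111                   0.009             0.078                 0.006
```

The ITS-derived profiles sit roughly an order of magnitude further from the
truth than the shotgun-derived ones at species level, and aggregating to
genus narrows the gap — the copy-number bias partially cancels when
congeneric species are pooled.

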