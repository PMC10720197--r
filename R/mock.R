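# In-silico mock communities for the ITS-vs-shotgun method comparison.
# Species pools mimic the study design: 27 strains across ~14 genera with
# known ITS copy numbers, assembled genomes carrying a collapsed (single)
# rDNA copy -- as real short-read assemblies do -- while the nominal copy
# number weights the amplicon simulator, exactly how the amplicon reads were
# generated from CN-replicated ITS sequences.

#' Build a mock species pool with genomes, ITS sequences and marker genes
#'
#' Each species gets a small single-contig genome containing two species-
#' specific single-copy marker genes and one rDNA copy (short flanks + a
#' species-specific ITS), plus a nominal ITS copy number drawn uniformly
#' from `cn_range` (the empirically observed intraspecific range).
#'
#' @param n_species pool size.
#' @param n_genera number of genera the species are spread over (several
#'   genera hold multiple species, which is what makes genus-level
#'   aggregation forgiving).
#' @param cn_range inclusive integer range of ITS copy numbers.
#' @param backbone_bp genome backbone length (bp).
#' @param marker_bp marker gene length; each species carries two markers.
#' @param its_bp ITS length.
#' @param seed integer seed.
#' @return object of class `mock_pool`: list with `species` (data frame:
#'   taxon, genus, cn, genome_length), `genomes`, `its`, `markers`,
#'   `marker_map` (gene -> species/genus), `lineage`.
#' @export
mock_species_pool <- function(n_species = 27, n_genera = 14,
                              cn_range = c(11, 137), backbone_bp = 6000,
                              marker_bp = 1000, its_bp = 550, seed = 1) {
  set.seed(seed)
  genus_of <- sort(c(seq_len(n_genera),
                     sample.int(n_genera, n_species - n_genera, replace = TRUE)))
  taxa <- sprintf("sp%02d", seq_len(n_species))
  genera <- sprintf("genus%02d", genus_of)
  cn <- sample(seq(cn_range[1], cn_range[2]), n_species, replace = TRUE)
  fl <- list(lsu = .random_dna(60), ssu = .random_dna(60))

  genomes <- list(); its <- character(0); markers <- character(0)
  marker_map <- list()
  for (i in seq_len(n_species)) {
    its_i <- .random_dna(its_bp)
    m1 <- .random_dna(marker_bp); m2 <- .random_dna(marker_bp)
    backbone <- .random_dna(backbone_bp)
    genome <- paste0(substr(backbone, 1, backbone_bp / 2), m1, m2,
                     fl$lsu, its_i, fl$ssu,
                     substr(backbone, backbone_bp / 2 + 1, backbone_bp))
    genomes[[taxa[i]]] <- setNames(genome, paste0(taxa[i], "_ctg1"))
    its[taxa[i]] <- its_i
    g1 <- paste0(taxa[i], "|marker1"); g2 <- paste0(taxa[i], "|marker2")
    markers[g1] <- m1; markers[g2] <- m2
    marker_map[[i]] <- data.frame(gene = c(g1, g2), species = taxa[i],
                                  genus = genera[i], stringsAsFactors = FALSE)
  }
  species <- data.frame(taxon = taxa, genus = genera, cn = cn,
                        genome_length = vapply(genomes, nchar, numeric(1)),
                        stringsAsFactors = FALSE)
  lineage <- data.frame(kingdom = "Fungi", genus = species$genus,
                        species = species$taxon, stringsAsFactors = FALSE)
  structure(list(species = species, genomes = genomes, its = its,
                 markers = markers,
                 marker_map = do.call(rbind, marker_map), lineage = lineage),
            class = "mock_pool")
}

#' Sample a mock community from a pool
#'
#' Randomly selects members and attributes random relative abundances
#' (uniform weights, normalized to sum 1).
#'
#' @param pool a [mock_species_pool()].
#' @param n_members number of member species.
#' @param seed integer seed.
#' @return object of class `mock_community`: list with `members` (data
#'   frame: taxon, genus, abundance, cn) and `genomes` (the members'
#'   genomes).
#' @export
sample_mock_community <- function(pool, n_members, seed = 1) {
  set.seed(seed)
  pick <- sort(sample.int(nrow(pool$species), n_members))
  sp <- pool$species[pick, , drop = FALSE]
  w <- runif(n_members, 0.5, 1.5)
  members <- data.frame(taxon = sp$taxon, genus = sp$genus,
                        abundance = w / sum(w), cn = sp$cn,
                        stringsAsFactors = FALSE)
  structure(list(members = members, genomes = pool$genomes[sp$taxon]),
            class = "mock_community")
}

#' Truth profile of a mock community
#'
#' @param community a `mock_community`.
#' @param level `"species"` or `"genus"`.
#' @return named abundance vector summing to 1.
#' @export
community_truth <- function(community, level = c("species", "genus")) {
  level <- match.arg(level)
  m <- community$members
  key <- if (level == "species") m$taxon else m$genus
  v <- tapply(m$abundance, key, sum)
  setNames(as.numeric(v), names(v))
}

#' Profile a mock community by the shotgun and ITS methods
#'
#' Simulates `n_reads` shotgun reads from the member genomes and `n_reads`
#' copy-number-weighted ITS amplicon reads, maps them to the pool-wide
#' marker-gene and ITS databases, converts end-trimmed mean depths to
#' relative abundances with the depth filter, and returns profiles at
#' species and genus level for both methods alongside the truth.
#'
#' @param community a [sample_mock_community()].
#' @param pool the [mock_species_pool()] the community was drawn from (its
#'   full marker and ITS databases are the mapping targets, so non-member
#'   hits become off-target).
#' @param n_reads reads per sequencing mode.
#' @param read_length,error_rate read simulation parameters.
#' @param min_depth depth filter applied to both methods.
#' @param mapq_min,trim depth pipeline parameters.
#' @param seed integer seed.
#' @return list with elements `truth`, `shotgun`, `its`, each a list with
#'   `species` and `genus` profiles.
#' @export
profile_mock_community <- function(community, pool, n_reads = 5e4,
                                   read_length = 100, error_rate = 0.005,
                                   min_depth = 15, mapq_min = 30, trim = 50,
                                   seed = 1) {
  expected_sp <- community$members$taxon
  expected_gen <- unique(community$members$genus)

  profile_of <- function(reads, refs, map, its_mode) {
    rec <- align_reads_minimal(reads, refs)
    dt <- depth_from_alignments(rec, mapq_min = mapq_min)
    gd <- gene_depths(dt, trim = trim)
    hits <- merge(gd, map, by.x = "ref", by.y = "gene")
    hits$gene <- hits$ref; hits$depth <- hits$trimmed_mean_depth
    lapply(c(species = "species", genus = "genus"), function(lev)
      depth_profile_to_abundance(hits, min_depth = min_depth, level = lev,
                                 expected_taxa = if (lev == "species")
                                   expected_sp else expected_gen))
  }

  sg_reads <- simulate_shotgun_reads(community, n_reads, read_length,
                                     error_rate, seed = seed)
  its_reads <- simulate_its_amplicons(community, pool$its, n_reads,
                                      read_length, error_rate,
                                      seed = seed + 1L)
  its_map <- data.frame(gene = names(pool$its),
                        species = names(pool$its),
                        genus = pool$species$genus[match(names(pool$its),
                                                         pool$species$taxon)],
                        stringsAsFactors = FALSE)
  list(
    truth = list(species = community_truth(community, "species"),
                 genus = community_truth(community, "genus")),
    shotgun = profile_of(sg_reads, pool$markers, pool$marker_map, FALSE),
    its = profile_of(its_reads, pool$its, its_map, TRUE))
}

#' Compare ITS and shotgun profiling accuracy over mock communities
#'
#' For each community, the weighted UniFrac distance between the truth and
#' each method's recovered profile is computed on the shared rank-lineage
#' tree, at species and genus level.
#'
#' @param pool a [mock_species_pool()].
#' @param n_communities number of mock communities.
#' @param members_range inclusive range of community sizes.
#' @param n_reads reads per mode per community.
#' @param seed integer seed.
#' @param ... further arguments to [profile_mock_community()].
#' @return data frame with one row per community: `unifrac_its_species`,
#'   `unifrac_shotgun_species`, `unifrac_its_genus`, `unifrac_shotgun_genus`.
#' @export
compare_profiling_methods <- function(pool, n_communities = 5,
                                      members_range = c(10, 14),
                                      n_reads = 5e4, seed = 1, ...) {
  set.seed(seed)
  sizes <- sample(seq(members_range[1], members_range[2]), n_communities,
                  replace = TRUE)
  seeds <- sample.int(1e6, 2 * n_communities)
  tree_sp <- lineage_tree(pool$lineage)
  tree_gen <- lineage_tree(unique(pool$lineage[c("kingdom", "genus")]))
  rows <- lapply(seq_len(n_communities), function(i) {
    comm <- sample_mock_community(pool, sizes[i], seed = seeds[i])
    pr <- profile_mock_community(comm, pool, n_reads = n_reads,
                                 seed = seeds[n_communities + i], ...)
    data.frame(
      community = i,
      unifrac_its_species = weighted_unifrac(pr$truth$species,
                                             pr$its$species, tree_sp),
      unifrac_shotgun_species = weighted_unifrac(pr$truth$species,
                                                 pr$shotgun$species, tree_sp),
      unifrac_its_genus = weighted_unifrac(pr$truth$genus, pr$its$genus,
                                           tree_gen),
      unifrac_shotgun_genus = weighted_unifrac(pr$truth$genus,
                                               pr$shotgun$genus, tree_gen))
  })
  do.call(rbind, rows)
}
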