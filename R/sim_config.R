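#' Configuration for the synthetic hybrid-genome generator
#'
#' Builds and validates the parameter set that drives every stage of the
#' synthetic-data module: two diverged parental subgenomes, a labeled donor
#' panel with lineage-private variation, planted introgression blocks of
#' known donor and zygosity, competitive-mapping depth profiles, and
#' clade-structured geography with isolation by distance.
#'
#' The defaults describe the reference scenario used throughout the package:
#' 6 clades of 10 diploid strains, 8 chromosomes of 50 one-kb genes,
#' two subgenomes at 12% divergence, 2 donor lineages delivering 2
#' introgression pulses, and a mean competitive-mapping depth of 150x.
#'
#' @param n_clades Number of focal-strain clades.
#' @param strains_per_clade Diploid strains per clade.
#' @param n_chromosomes Chromosomes per subgenome.
#' @param genes_per_chromosome Genes per chromosome.
#' @param gene_length Gene length in bp.
#' @param intergenic_length Intergenic spacer length in bp.
#' @param parental_divergence Fraction of sites differing between the two
#'   subgenome references.
#' @param n_donor_lineages Number of donor lineages in the panel.
#' @param donors_per_lineage Panel strains per lineage.
#' @param donor_private_divergence Per-bp rate of variants private to each
#'   donor lineage.
#' @param donor_shared_divergence Per-bp rate of variation shared across the
#'   donor panel (segregating at random frequency).
#' @param donor_within_noise Per-bp rate of variants private to a single
#'   panel strain (within-lineage variation).
#' @param n_pulses Number of introgression pulses; clades are distributed
#'   round-robin over pulses and each pulse draws from one donor lineage.
#' @param shared_blocks_per_pulse Ancestral blocks planted identically in
#'   every strain of a pulse's clades.
#' @param block_rate Expected number of strain-private planted blocks per
#'   strain (Poisson).
#' @param block_length_mean Mean block length in genes (shifted geometric).
#' @param het_fraction Fraction of planted blocks that are heterozygous.
#' @param mean_depth Expected per-position coverage of the resident genome.
#' @param depth_model `"noiseless"` or `"poisson"`.
#' @param background_site_rate Per-bp rate of background SNPs on the
#'   resident (S. cerevisiae) subgenome.
#' @param background_missing_rate Per-cell missing-genotype rate at
#'   background sites.
#' @param clade_drift_sd Standard deviation of clade-level logit-frequency
#'   drift at background sites.
#' @param ibd_strength Slope tying clade geography to background allele
#'   frequencies (0 removes isolation by distance).
#' @param geo_jitter_sd Within-clade geographic jitter, degrees.
#' @param seed Integer RNG seed; all stochastic draws derive from it.
#'
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_clades = 6,
                       strains_per_clade = 10,
                       n_chromosomes = 8,
                       genes_per_chromosome = 50,
                       gene_length = 1000,
                       intergenic_length = 200,
                       parental_divergence = 0.12,
                       n_donor_lineages = 2,
                       donors_per_lineage = 3,
                       donor_private_divergence = 0.02,
                       donor_shared_divergence = 0.01,
                       donor_within_noise = 0.002,
                       n_pulses = 2,
                       shared_blocks_per_pulse = 1,
                       block_rate = 2,
                       block_length_mean = 5,
                       het_fraction = 0.3,
                       mean_depth = 150,
                       depth_model = c("noiseless", "poisson"),
                       background_site_rate = 0.005,
                       background_missing_rate = 0.02,
                       clade_drift_sd = 0.5,
                       ibd_strength = 1,
                       geo_jitter_sd = 0.3,
                       seed = 1) {
  depth_model <- match.arg(depth_model)
  cfg <- list(
    n_clades = n_clades, strains_per_clade = strains_per_clade,
    n_chromosomes = n_chromosomes, genes_per_chromosome = genes_per_chromosome,
    gene_length = gene_length, intergenic_length = intergenic_length,
    parental_divergence = parental_divergence,
    n_donor_lineages = n_donor_lineages, donors_per_lineage = donors_per_lineage,
    donor_private_divergence = donor_private_divergence,
    donor_shared_divergence = donor_shared_divergence,
    donor_within_noise = donor_within_noise,
    n_pulses = n_pulses, shared_blocks_per_pulse = shared_blocks_per_pulse,
    block_rate = block_rate, block_length_mean = block_length_mean,
    het_fraction = het_fraction,
    mean_depth = mean_depth, depth_model = depth_model,
    background_site_rate = background_site_rate,
    background_missing_rate = background_missing_rate,
    clade_drift_sd = clade_drift_sd,
    ibd_strength = ibd_strength, geo_jitter_sd = geo_jitter_sd,
    seed = seed
  )
  validate_sim_config(cfg)
  class(cfg) <- "sim_config"
  cfg
}

validate_sim_config <- function(cfg) {
  for (nm in c("n_clades", "strains_per_clade", "n_chromosomes",
               "genes_per_chromosome", "gene_length", "intergenic_length",
               "donors_per_lineage", "n_pulses")) {
    abort_if(!is_count(cfg[[nm]]), "sim_config: `", nm,
             "` must be a positive integer")
  }
  for (nm in c("parental_divergence", "donor_private_divergence",
               "donor_shared_divergence", "donor_within_noise",
               "het_fraction", "background_site_rate",
               "background_missing_rate")) {
    abort_if(!is_fraction(cfg[[nm]]), "sim_config: `", nm,
             "` must be a fraction in [0, 1]")
  }
  abort_if(!is_count(cfg$n_donor_lineages), "sim_config: `n_donor_lineages` must be a positive integer")
  abort_if(cfg$block_rate < 0, "sim_config: `block_rate` must be >= 0")
  abort_if(cfg$block_length_mean < 1, "sim_config: `block_length_mean` must be >= 1 gene")
  abort_if(cfg$mean_depth <= 0, "sim_config: `mean_depth` must be > 0")
  abort_if(cfg$ibd_strength < 0, "sim_config: `ibd_strength` must be >= 0")
  abort_if(!is_count(abs(cfg$seed) + 1), "sim_config: `seed` must be an integer")
  invisible(cfg)
}

#' Scenario presets with one, two, or three introgression pulses
#'
#' The pulse history of real introgressed populations is unknown; these
#' presets expose alternative histories (a single ancestral pulse, or two or
#' three lineage-specific pulses) without asserting any one as correct.
#'
#' @param n_pulses 1, 2, or 3.
#' @param ... Overrides forwarded to [sim_config()].
#' @return A `sim_config`.
#' @export
scenario_preset <- function(n_pulses = 2, ...) {
  abort_if(!n_pulses %in% 1:3, "scenario_preset: n_pulses must be 1, 2 or 3")
  sim_config(n_pulses = n_pulses,
             n_donor_lineages = max(2, n_pulses), ...)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>\n")
  cat(sprintf("  %d clades x %d strains; %d chr x %d genes (%d bp + %d bp spacer)\n",
              x$n_clades, x$strains_per_clade, x$n_chromosomes,
              x$genes_per_chromosome, x$gene_length, x$intergenic_length))
  cat(sprintf("  parental divergence %.3f; %d donor lineages; %d pulse(s)\n",
              x$parental_divergence, x$n_donor_lineages, x$n_pulses))
  cat(sprintf("  depth %s, mean %g; seed %d\n", x$depth_model, x$mean_depth,
              as.integer(x$seed)))
  invisible(x)
}
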