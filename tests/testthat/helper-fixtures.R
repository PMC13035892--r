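# Small shared fixtures, all built in code.

tiny_config <- function(...) {
  args <- list(n_clades = 2, strains_per_clade = 3, n_chromosomes = 2,
               genes_per_chromosome = 15, gene_length = 300,
               intergenic_length = 100, seed = 11)
  dots <- list(...)
  args[names(dots)] <- dots
  do.call(sim_config, args)
}

# genotype matrix from a dosage matrix (sites x strains); default clean
# biallelic SNP metadata
toy_gm <- function(gt, pos = NULL, chrom = "Scer_chr01", qual = 1000,
                   dp = NULL, ref = "A", alt = "C") {
  gt <- as.matrix(gt)
  if (is.null(colnames(gt)))
    colnames(gt) <- paste0("s", seq_len(ncol(gt)))
  n <- nrow(gt)
  sites <- tibble::tibble(
    chrom = rep_len(chrom, n),
    pos = if (is.null(pos)) seq_len(n) else pos,
    ref = rep_len(ref, n), alt = rep_len(alt, n),
    qual = rep_len(qual, n))
  genotype_matrix(sites, gt, dp)
}

# brute-force nucleotide diversity: per site, differing haplotype pairs
# over all called pairs, summed and divided by the window span
oracle_pi <- function(gt, span) {
  tot <- 0
  for (s in seq_len(nrow(gt))) {
    g <- gt[s, ]
    g <- g[!is.na(g)]
    k <- 2 * length(g)
    if (k < 2) next
    j <- sum(g)
    hap <- c(rep(1, j), rep(0, k - j))
    diffs <- 0
    for (a in seq_len(k - 1)) for (b in (a + 1):k)
      diffs <- diffs + (hap[a] != hap[b])
    tot <- tot + diffs / choose(k, 2)
  }
  tot / span
}

# greedy LD pruning reimplemented naively (variant-count windows)
oracle_ld_prune <- function(gt, window, step, r2_max) {
  n <- nrow(gt)
  keep <- rep(TRUE, n)
  for (s in seq(1, n, by = step)) {
    idx <- s:min(s + window - 1, n)
    for (j in idx) {
      if (!keep[j]) next
      for (i in idx[idx < j]) {
        if (!keep[i]) next
        r <- suppressWarnings(stats::cor(gt[i, ], gt[j, ],
                                         use = "pairwise.complete.obs"))
        if (isTRUE(r^2 > r2_max)) { keep[j] <- FALSE; break }
      }
    }
  }
  which(keep)
}
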