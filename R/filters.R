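#' Apply the standard site filters to a genotype matrix
#'
#' Reproduces the variant-level filtering used throughout the analysis, in
#' a fixed order: (1) genotype cells with depth below `min_depth` are set
#' to missing; (2) sites with QUAL below `min_qual` are dropped; (3) only
#' biallelic single-nucleotide sites are kept; (4) sites called in fewer
#' than `min_call_rate` of the strains are dropped. The order is pinned
#' because depth masking changes call rates. The filter is idempotent.
#'
#' @param gm A [genotype_matrix()].
#' @param min_depth Minimum per-cell depth; lower cells become missing.
#' @param min_qual Minimum site QUAL (inclusive).
#' @param min_call_rate Minimum fraction of strains called (inclusive).
#' @return A filtered `genotype_matrix`.
#' @export
filter_sites <- function(gm, min_depth = 5, min_qual = 30,
                         min_call_rate = 0.90) {
  gt <- gm$gt
  dp <- gm$dp
  if (!is.null(dp)) {
    gt[is.na(dp) | dp < min_depth] <- NA_integer_
  }
  keep_qual <- !is.na(gm$sites$qual) & gm$sites$qual >= min_qual
  single <- function(x) !is.na(x) & nchar(x) == 1L & x %in% DNA_BASES
  keep_snp <- single(gm$sites$ref) & single(gm$sites$alt)
  call_rate <- rowMeans(!is.na(gt))
  keep <- keep_qual & keep_snp & call_rate >= min_call_rate
  genotype_matrix(gm$sites[keep, , drop = FALSE],
                  gt[keep, , drop = FALSE],
                  if (!is.null(dp)) dp[keep, , drop = FALSE])
}

#' Missingness filters for population-structure analyses
#'
#' First drops sites whose missing call rate exceeds `max_site_missing`,
#' then drops strains whose remaining missing fraction exceeds
#' `max_strain_missing` — in that order, since the strain pass is defined
#' on the site-filtered matrix.
#'
#' @param gm A [genotype_matrix()].
#' @param max_site_missing Maximum tolerated per-site missing fraction.
#' @param max_strain_missing Maximum tolerated per-strain missing fraction.
#' @return A reduced `genotype_matrix`.
#' @export
filter_for_structure <- function(gm, max_site_missing = 0.01,
                                 max_strain_missing = 0.10) {
  site_miss <- rowMeans(is.na(gm$gt))
  keep_sites <- site_miss <= max_site_missing
  abort_if(!any(keep_sites), "filter_for_structure: no sites survive")
  gt <- gm$gt[keep_sites, , drop = FALSE]
  strain_miss <- colMeans(is.na(gt))
  keep_strains <- strain_miss <= max_strain_missing
  abort_if(!any(keep_strains), "filter_for_structure: no strains survive")
  gm_subset(gm, sites = keep_sites, strains = gm$strains[keep_strains])
}

#' Greedy linkage-disequilibrium pruning
#'
#' Within each sliding window, any pair of retained sites with genotype
#' correlation r-squared above `r2_max` loses its later member (positional
#' order), then the window slides by `step`; windows never span
#' chromosomes. With `unit = "variants"` window and step count variants
#' (the convention of the standard pruning tool); with `unit = "bp"` they
#' are measured in base pairs. Deterministic given input order.
#'
#' @param gm A [genotype_matrix()].
#' @param window Window size (variants or bp).
#' @param step Slide increment (variants or bp).
#' @param r2_max Maximum tolerated pairwise r-squared.
#' @param unit `"variants"` or `"bp"`.
#' @return Integer vector of retained site indices (rows of `gm$sites`).
#' @export
ld_prune <- function(gm, window = 50, step = 5, r2_max = 0.5,
                     unit = c("variants", "bp")) {
  unit <- match.arg(unit)
  keep <- rep(TRUE, nrow(gm$sites))
  for (cn in unique(gm$sites$chrom)) {
    ci <- which(gm$sites$chrom == cn)
    ci <- ci[order(gm$sites$pos[ci])]
    n <- length(ci)
    if (n < 2) next
    starts <- if (unit == "variants") {
      lapply(seq(1L, n, by = step), function(s) s:min(s + window - 1L, n))
    } else {
      pos <- gm$sites$pos[ci]
      lapply(seq(min(pos), max(pos), by = step), function(s)
        which(pos >= s & pos < s + window))
    }
    for (idx in starts) {
      idx <- idx[keep[ci[idx]]]
      if (length(idx) < 2) next
      g <- gm$gt[ci[idx], , drop = FALSE]
      r2 <- suppressWarnings(
        stats::cor(t(g), use = "pairwise.complete.obs"))^2
      for (j in 2:length(idx)) {
        if (!keep[ci[idx[j]]]) next
        for (i in 1:(j - 1)) {
          if (!keep[ci[idx[i]]]) next
          if (isTRUE(r2[i, j] > r2_max)) {
            keep[ci[idx[j]]] <- FALSE
            break
          }
        }
      }
    }
  }
  which(keep)
}
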