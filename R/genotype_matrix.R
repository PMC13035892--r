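#' Genotype matrix container
#'
#' Holds biallelic SNP sites with per-strain allele dosages and depths.
#' Sites are rows (VCF order), strains are columns. Dosage coding is
#' 0 = hom ref, 1 = het, 2 = hom alt, `NA` = missing; half-called genotypes
#' are treated as missing.
#'
#' @param sites Tibble with columns `chrom`, `pos`, `ref`, `alt`, `qual`.
#' @param gt Integer matrix (sites x strains) of dosages; column names are
#'   strain identifiers.
#' @param dp Optional numeric matrix of per-cell read depths, same shape.
#'
#' @return An object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(sites, gt, dp = NULL) {
  sites <- tibble::as_tibble(sites)
  abort_if(!all(c("chrom", "pos", "ref", "alt", "qual") %in% names(sites)),
           "genotype_matrix: sites must have chrom, pos, ref, alt, qual")
  gt <- as.matrix(gt)
  abort_if(nrow(gt) != nrow(sites),
           "genotype_matrix: gt rows must match sites")
  abort_if(is.null(colnames(gt)), "genotype_matrix: gt must have strain column names")
  if (!is.null(dp)) {
    dp <- as.matrix(dp)
    abort_if(!all(dim(dp) == dim(gt)), "genotype_matrix: dp shape must match gt")
  }
  abort_if(any(sites$pos < 1), "genotype_matrix: positions must be >= 1")
  structure(list(sites = sites, gt = gt, dp = dp,
                 strains = colnames(gt)),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("<genotype_matrix> %d sites x %d strains (%.1f%% missing)\n",
              nrow(x$sites), length(x$strains),
              100 * mean(is.na(x$gt))))
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$gt)

#' Subset a genotype matrix by sites and/or strains
#'
#' @param gm A [genotype_matrix()].
#' @param sites Row index (logical or integer) into the site table.
#' @param strains Column index or strain names.
#' @return A `genotype_matrix`.
#' @export
gm_subset <- function(gm, sites = NULL, strains = NULL) {
  if (is.null(sites)) sites <- seq_len(nrow(gm$sites))
  if (is.null(strains)) strains <- gm$strains
  gt <- gm$gt[sites, , drop = FALSE][, strains, drop = FALSE]
  dp <- if (!is.null(gm$dp)) gm$dp[sites, , drop = FALSE][, strains, drop = FALSE]
  genotype_matrix(gm$sites[sites, , drop = FALSE], gt, dp)
}

#' Combine two genotype matrices over the same strains
#' @noRd
gm_rbind <- function(a, b) {
  abort_if(!identical(a$strains, b$strains),
           "gm_rbind: strain sets must match")
  sites <- rbind(a$sites, b$sites)
  gt <- rbind(a$gt, b$gt)
  dp <- if (!is.null(a$dp) && !is.null(b$dp)) rbind(a$dp, b$dp)
  ord <- order(sites$chrom, sites$pos)
  genotype_matrix(sites[ord, ], gt[ord, , drop = FALSE],
                  if (!is.null(dp)) dp[ord, , drop = FALSE])
}

#' Restrict a genotype matrix to one subgenome by contig prefix
#'
#' @param gm A [genotype_matrix()].
#' @param prefix Contig-name prefix, e.g. `"Scer_"` or `"Spar_"`.
#' @return A `genotype_matrix` with only matching sites.
#' @export
gm_subgenome <- function(gm, prefix) {
  gm_subset(gm, sites = startsWith(gm$sites$chrom, prefix))
}
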