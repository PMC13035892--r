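#' Identity-by-state between a focal block and each donor-panel strain
#'
#' Restricted to paradoxus-subgenome variant sites inside the block's
#' genes, per-site IBS between two diploid genotypes is the number of
#' shared alleles divided by 2 (equivalently `1 - |dosage_a - dosage_b|/2`),
#' averaged over sites called in both genotypes (pairwise deletion).
#'
#' @param focal_gm Focal [genotype_matrix()].
#' @param strain Focal strain identifier.
#' @param block One row of a block table.
#' @param annotation Annotation tibble.
#' @param panel_gm Donor-panel [genotype_matrix()] on the same contigs.
#' @return Named numeric vector of IBS values, one per panel strain;
#'   panel strains with no co-called site are skipped with a warning.
#' @export
region_ibs <- function(focal_gm, strain, block, annotation, panel_gm) {
  fi <- block_site_index(focal_gm, block, annotation)
  pi_ <- block_site_index(panel_gm, block, annotation)
  fk <- paste(focal_gm$sites$chrom[fi], focal_gm$sites$pos[fi])
  pk <- paste(panel_gm$sites$chrom[pi_], panel_gm$sites$pos[pi_])
  common <- intersect(fk, pk)
  f <- focal_gm$gt[fi[match(common, fk)], strain]
  P <- panel_gm$gt[pi_[match(common, pk)], , drop = FALSE]
  out <- stats::setNames(rep(NA_real_, ncol(P)), colnames(P))
  for (s in colnames(P)) {
    ok <- !is.na(f) & !is.na(P[, s])
    if (!any(ok)) {
      warning("region_ibs: no co-called sites with panel strain ", s,
              "; skipped", call. = FALSE)
      next
    }
    out[s] <- mean(1 - abs(f[ok] - P[ok, s]) / 2)
  }
  out
}

#' Assign a block's donor origin from per-strain IBS values
#'
#' The block is assigned to the lineage (clade) of the panel strain with
#' the highest IBS. When the best IBS values of two or more distinct
#' lineages agree within `tie_tol`, no origin is assigned. A single-lineage
#' panel yields an assignment flagged low-confidence.
#'
#' @param ibs Named IBS vector from [region_ibs()].
#' @param lineages Tibble with `strain` and `lineage`.
#' @param tie_tol Absolute IBS tie tolerance.
#' @return One-row tibble: `origin` (lineage or `"unassigned"`),
#'   `best_strain`, `best_ibs`, `runner_up_origin`, `runner_up_ibs`,
#'   `assigned`, `note`.
#' @export
assign_block_origin <- function(ibs, lineages, tie_tol = 1e-6) {
  unassigned <- function(note) tibble::tibble(
    origin = "unassigned", best_strain = NA_character_,
    best_ibs = NA_real_, runner_up_origin = NA_character_,
    runner_up_ibs = NA_real_, assigned = FALSE, note = note)
  ibs <- ibs[!is.na(ibs)]
  if (length(ibs) == 0) return(unassigned("no usable IBS values"))
  lin <- lineages$lineage[match(names(ibs), lineages$strain)]
  by_lin <- tapply(ibs, lin, max)
  ord <- order(by_lin, decreasing = TRUE)
  best_lin <- names(by_lin)[ord[1]]
  best_strain <- names(ibs)[lin == best_lin][
    which.max(ibs[lin == best_lin])]
  if (length(by_lin) == 1) {
    return(tibble::tibble(origin = best_lin, best_strain = best_strain,
                          best_ibs = unname(by_lin[1]),
                          runner_up_origin = NA_character_,
                          runner_up_ibs = NA_real_, assigned = TRUE,
                          note = "low-confidence: single-lineage panel"))
  }
  ru <- ord[2]
  if (by_lin[ord[1]] - by_lin[ru] <= tie_tol) {
    out <- unassigned("tie between lineages")
    out$best_ibs <- unname(by_lin[ord[1]])
    out$runner_up_origin <- names(by_lin)[ru]
    out$runner_up_ibs <- unname(by_lin[ru])
    return(out)
  }
  tibble::tibble(origin = best_lin, best_strain = best_strain,
                 best_ibs = unname(by_lin[ord[1]]),
                 runner_up_origin = names(by_lin)[ru],
                 runner_up_ibs = unname(by_lin[ru]),
                 assigned = TRUE, note = NA_character_)
}

#' Assign donor origins to every block
#'
#' @param blocks Block table (from [assemble_blocks()], optionally after
#'   [validate_blocks()]).
#' @param focal_gm Focal [genotype_matrix()].
#' @param annotation Annotation tibble.
#' @param panel_gm Donor-panel [genotype_matrix()].
#' @param lineages Donor lineage tibble.
#' @param tie_tol Tie tolerance.
#' @return `blocks` with origin columns appended.
#' @export
assign_block_origins <- function(blocks, focal_gm, annotation, panel_gm,
                                 lineages, tie_tol = 1e-6) {
  if (nrow(blocks) == 0) {
    for (nm in c("origin", "best_strain", "runner_up_origin", "note"))
      blocks[[nm]] <- character(0)
    for (nm in c("best_ibs", "runner_up_ibs")) blocks[[nm]] <- numeric(0)
    blocks$assigned <- logical(0)
    return(blocks)
  }
  res <- lapply(seq_len(nrow(blocks)), function(b) {
    ibs <- suppressWarnings(
      region_ibs(focal_gm, blocks$strain[b], blocks[b, ], annotation,
                 panel_gm))
    assign_block_origin(ibs, lineages, tie_tol)
  })
  res <- do.call(rbind, res)
  for (nm in names(res)) blocks[[nm]] <- res[[nm]]
  blocks
}

#' Propagate a block's origin to its genes
#'
#' Every gene within a block inherits the block's origin verbatim;
#' unassigned blocks yield unassigned genes.
#'
#' @param blocks Block table with origin columns
#'   (see [assign_block_origins()]).
#' @return Tibble with `strain`, `gene_id`, `block_id`, `origin`.
#' @export
propagate_block_origin <- function(blocks) {
  if (nrow(blocks) == 0)
    return(tibble::tibble(strain = character(0), gene_id = character(0),
                          block_id = character(0), origin = character(0)))
  n <- blocks$n_genes
  tibble::tibble(
    strain = rep(blocks$strain, n),
    gene_id = unlist(blocks$gene_ids),
    block_id = rep(blocks$block_id, n),
    origin = rep(blocks$origin, n))
}

#' Donor-lineage assignment by phylogenetic (p-) distance
#'
#' Concordance check for the IBS route: aligns the focal block haplotype
#' against the donor panel members' sequences and assigns the lineage of
#' the panel strain at minimum p-distance; ties yield `"unassigned"`.
#'
#' @param gm Focal [genotype_matrix()].
#' @param strain Focal strain identifier.
#' @param block One row of a block table.
#' @param annotation Annotation tibble.
#' @param donor_genomes Named list of donor genomes over `Spar_` contigs
#'   (see [donor_panel_genomes()]).
#' @param lineages Donor lineage tibble.
#' @param tol Distance tie tolerance.
#' @return Lineage label or `"unassigned"`.
#' @export
assign_origin_by_tree_distance <- function(gm, strain, block, annotation,
                                           donor_genomes, lineages,
                                           tol = 1e-9) {
  panel <- list(members = tibble::tibble(member = names(donor_genomes),
                                         species = "paradoxus"),
                genomes = donor_genomes)
  # the alignment backbone needs the paradoxus reference under "par_ref"
  abort_if(!"par_ref" %in% names(donor_genomes),
           "assign_origin_by_tree_distance: donor_genomes must include par_ref")
  aln <- block_alignment(gm, strain, block, annotation, panel)
  if (is.null(aln)) return("unassigned")
  D <- pdistance_matrix(aln)
  d <- D["focal", setdiff(colnames(D), c("focal", "par_ref"))]
  lin <- lineages$lineage[match(names(d), lineages$strain)]
  by_lin <- tapply(d, lin, min)
  ord <- order(by_lin)
  if (length(by_lin) > 1 && by_lin[ord[2]] - by_lin[ord[1]] <= tol)
    return("unassigned")
  names(by_lin)[ord[1]]
}

#' Donor-panel genomes over paradoxus coordinates
#'
#' @param parental Output of [simulate_parental_genomes()].
#' @param donor Output of [simulate_donor_panel()].
#' @return Named list: `par_ref` plus one genome per panel strain.
#' @export
donor_panel_genomes <- function(parental, donor) {
  par_chroms <- grep("^Spar_", names(parental$genomes), value = TRUE)
  par_ref <- parental$genomes[par_chroms]
  out <- list(par_ref = par_ref)
  for (s in donor$lineages$strain)
    out[[s]] <- apply_variants(par_ref, donor$gm, s)
  out
}

#' Per-strain and per-clade donor-lineage gene counts
#'
#' @param gene_origins Tibble from [propagate_block_origin()].
#' @param roster Strain/clade tibble.
#' @return A list with `per_strain` (strain x origin counts) and
#'   `per_clade` (clade x origin totals); unassigned genes are reported
#'   under `"unassigned"`.
#' @export
summarize_origin_counts <- function(gene_origins, roster) {
  if (nrow(gene_origins) == 0) {
    return(list(per_strain = tibble::tibble(strain = character(0),
                                            origin = character(0),
                                            n_genes = integer(0)),
                per_clade = tibble::tibble(clade = character(0),
                                           origin = character(0),
                                           n_genes = integer(0))))
  }
  per_strain <- as.data.frame(table(strain = gene_origins$strain,
                                    origin = gene_origins$origin),
                              stringsAsFactors = FALSE)
  per_strain <- tibble::as_tibble(per_strain[per_strain$Freq > 0, ])
  names(per_strain)[3] <- "n_genes"
  gene_origins$clade <- roster$clade[match(gene_origins$strain,
                                           roster$strain)]
  per_clade <- as.data.frame(table(clade = gene_origins$clade,
                                   origin = gene_origins$origin),
                             stringsAsFactors = FALSE)
  per_clade <- tibble::as_tibble(per_clade[per_clade$Freq > 0, ])
  names(per_clade)[3] <- "n_genes"
  list(per_strain = per_strain, per_clade = per_clade)
}
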