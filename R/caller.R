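#' Summarize per-position depths into per-gene coverage statistics
#'
#' For each strain: the median depth of the reference (over the resident
#' subgenome by default, or the whole concatenated reference), then per
#' gene the fraction of positions with depth strictly exceeding
#' `depth_factor` times that median, and the mean depth over the gene.
#' Positions absent from the input are counted as depth 0 (gene length
#' comes from the annotation).
#'
#' @param pos_depths Tibble with `strain`, `chrom`, `pos`, `depth` (e.g.
#'   from [simulate_position_depths()] or [read_depth_bed()]).
#' @param annotation Annotation tibble.
#' @param depth_factor Multiplier of the strain median defining "covered".
#' @param median_scope `"resident"` (default): median over contigs with
#'   `resident_prefix`; `"concatenated"`: over all positions supplied.
#' @param resident_prefix Contig prefix of the resident subgenome.
#' @return Tibble of per-strain per-gene summaries (see
#'   [simulate_depths()] for columns). Strains with median depth 0 are
#'   excluded with a warning.
#' @export
summarize_gene_depths <- function(pos_depths, annotation,
                                  depth_factor = 0.25,
                                  median_scope = c("resident", "concatenated"),
                                  resident_prefix = "Scer_") {
  median_scope <- match.arg(median_scope)
  out <- list()
  for (s in unique(pos_depths$strain)) {
    d <- pos_depths[pos_depths$strain == s, ]
    scope <- if (median_scope == "resident")
      d[startsWith(d$chrom, resident_prefix), ] else d
    med <- stats::median(scope$depth)
    if (!is.finite(med) || med <= 0) {
      warning("summarize_gene_depths: strain ", s,
              " has median depth 0; excluded", call. = FALSE)
      next
    }
    thr <- depth_factor * med
    rows <- lapply(seq_len(nrow(annotation)), function(g) {
      gene <- annotation[g, ]
      dd <- d$depth[d$chrom == gene$chrom & d$pos >= gene$start &
                      d$pos <= gene$end]
      len <- gene$end - gene$start + 1L
      tibble::tibble(strain = s, gene_id = gene$gene_id,
                     subgenome = gene$subgenome,
                     frac_above_threshold = sum(dd > thr) / len,
                     gene_depth = sum(dd) / len,
                     strain_median = med)
    })
    out[[s]] <- do.call(rbind, rows)
  }
  abort_if(length(out) == 0, "summarize_gene_depths: no analyzable strains")
  do.call(rbind, out)
}

#' Call per-gene introgression state from competitive-mapping summaries
#'
#' A paradoxus-subgenome gene is called introgressed in a strain iff
#' (i) strictly more than `min_covered_frac` of its positions exceed the
#' covered-depth threshold, AND (ii) its depth is the highest of its
#' ortholog pair or at least `ortholog_depth_factor` times the depth of
#' its cerevisiae ortholog, AND (iii) the nucleotide divergence of the
#' ortholog pair is at least `min_divergence`. Called genes are classified
#' heterozygous or homozygous by the subgenome depth ratio (see
#' [classify_zygosity()]). Genes without a 1:1 ortholog are skipped.
#'
#' @param summaries Per-gene depth summaries (see [simulate_depths()]).
#' @param annotation Annotation tibble.
#' @param min_covered_frac Covered-fraction threshold (strict `>`).
#' @param ortholog_depth_factor Minimum depth relative to the ortholog
#'   (inclusive `>=`).
#' @param min_divergence Minimum ortholog divergence (inclusive `>=`).
#' @param het_ratio_low,het_ratio_high Closed heterozygosity interval for
#'   the paradoxus/cerevisiae depth ratio.
#' @return Tibble with one row per strain and paradoxus gene: `strain`,
#'   `gene_id`, `state` (`absent`, `introgressed_hom`, `introgressed_het`)
#'   and `depth_ratio` (`Inf` when the ortholog depth is 0).
#' @export
call_introgressed_genes <- function(summaries, annotation,
                                    min_covered_frac = 0.5,
                                    ortholog_depth_factor = 0.25,
                                    min_divergence = 0.05,
                                    het_ratio_low = 0.25,
                                    het_ratio_high = 4.0) {
  par_ann <- annotation[annotation$subgenome == "par", ]
  skipped <- par_ann$gene_id[is.na(par_ann$ortholog_id)]
  if (length(skipped) > 0) {
    message("call_introgressed_genes: skipping ", length(skipped),
            " paradoxus gene(s) without an ortholog pairing")
    par_ann <- par_ann[!is.na(par_ann$ortholog_id), ]
  }
  psum <- summaries[summaries$gene_id %in% par_ann$gene_id, ]
  key <- function(s, g) paste(s, g)
  cer_depth <- stats::setNames(summaries$gene_depth,
                               key(summaries$strain, summaries$gene_id))
  i <- match(psum$gene_id, par_ann$gene_id)
  ortho <- par_ann$ortholog_id[i]
  div <- par_ann$ortholog_divergence[i]
  cd <- cer_depth[key(psum$strain, ortho)]
  abort_if(any(is.na(cd)),
           "call_introgressed_genes: missing ortholog depth summaries")
  pd <- psum$gene_depth
  covered <- psum$frac_above_threshold > min_covered_frac
  depth_ok <- (pd > cd) | (pd >= ortholog_depth_factor * cd)
  div_ok <- div >= min_divergence
  called <- covered & depth_ok & div_ok
  ratio <- unname(ifelse(cd == 0, Inf, pd / cd))
  state <- rep("absent", nrow(psum))
  if (any(called))
    state[called] <- classify_zygosity(ratio[called], het_ratio_low,
                                       het_ratio_high)
  tibble::tibble(strain = psum$strain, gene_id = psum$gene_id,
                 state = state, depth_ratio = ratio)
}

#' Classify zygosity of called introgressed genes from the depth ratio
#'
#' The ratio is paradoxus gene depth divided by cerevisiae ortholog depth.
#' A ratio inside the closed interval `[het_ratio_low, het_ratio_high]`
#' means both orthologs retain substantial coverage, i.e. one haplotype of
#' each: heterozygous. A ratio above the interval (including infinite, when
#' the cerevisiae copy has no coverage) means the cerevisiae copy was
#' replaced on both haplotypes: homozygous. Ratios below the interval
#' cannot occur for genes that passed the calling rules.
#'
#' @param depth_ratio Numeric vector of depth ratios (may contain `Inf`).
#' @param het_ratio_low,het_ratio_high Closed interval bounds.
#' @return Character vector, `"introgressed_het"` or `"introgressed_hom"`.
#' @export
classify_zygosity <- function(depth_ratio, het_ratio_low = 0.25,
                              het_ratio_high = 4.0) {
  abort_if(any(depth_ratio < het_ratio_low, na.rm = TRUE),
           "classify_zygosity: ratio below ", het_ratio_low,
           " is impossible for a called gene")
  ifelse(depth_ratio <= het_ratio_high, "introgressed_het",
         "introgressed_hom")
}

#' Assemble called genes into contiguous introgression blocks
#'
#' Maximal runs of consecutive (by annotation order) introgressed genes on
#' one chromosome form one block; there is no gap tolerance and blocks
#' never span chromosomes.
#'
#' @param calls Call table from [call_introgressed_genes()].
#' @param annotation Annotation tibble.
#' @return Tibble with `block_id`, `strain`, `chrom`, `first_index`,
#'   `n_genes`, `gene_ids` (list column), `start`, `end`, `any_het`.
#' @export
assemble_blocks <- function(calls, annotation) {
  intro <- calls[calls$state != "absent", ]
  empty <- tibble::tibble(block_id = character(0), strain = character(0),
                          chrom = character(0), first_index = integer(0),
                          n_genes = integer(0), gene_ids = list(),
                          start = integer(0), end = integer(0),
                          any_het = logical(0))
  if (nrow(intro) == 0) return(empty)
  i <- match(intro$gene_id, annotation$gene_id)
  intro$chrom <- annotation$chrom[i]
  intro$order_index <- annotation$order_index[i]
  intro$start <- annotation$start[i]
  intro$end <- annotation$end[i]
  intro <- intro[order(intro$strain, intro$chrom, intro$order_index), ]
  new_run <- c(TRUE, intro$strain[-1] != intro$strain[-nrow(intro)] |
                 intro$chrom[-1] != intro$chrom[-nrow(intro)] |
                 diff(intro$order_index) != 1L)
  parts <- split(seq_len(nrow(intro)), cumsum(new_run))
  out <- do.call(rbind, lapply(parts, function(ii) {
    x <- intro[ii, ]
    tibble::tibble(strain = x$strain[1], chrom = x$chrom[1],
                   first_index = x$order_index[1], n_genes = nrow(x),
                   gene_ids = list(x$gene_id),
                   start = min(x$start), end = max(x$end),
                   any_het = any(x$state == "introgressed_het"))
  }))
  out$block_id <- sprintf("%s:%s:%d", out$strain, out$chrom, out$first_index)
  out[, c("block_id", "strain", "chrom", "first_index", "n_genes",
          "gene_ids", "start", "end", "any_het")]
}

#' Per-strain introgression totals
#'
#' @param calls Call table from [call_introgressed_genes()].
#' @param blocks Optional block table from [assemble_blocks()]; adds block
#'   count and length statistics.
#' @return Tibble with per-strain introgressed-gene count, heterozygous
#'   count and heterozygous fraction (`NA` when the count is 0).
#' @export
summarize_strain_introgression <- function(calls, blocks = NULL) {
  strains <- unique(calls$strain)
  n <- vapply(strains, function(s)
    sum(calls$state != "absent" & calls$strain == s), numeric(1),
    USE.NAMES = FALSE)
  nh <- vapply(strains, function(s)
    sum(calls$state == "introgressed_het" & calls$strain == s), numeric(1),
    USE.NAMES = FALSE)
  out <- tibble::tibble(strain = strains, n_introgressed = n, n_het = nh,
                        het_fraction = ifelse(n > 0, nh / n, NA_real_))
  if (!is.null(blocks)) {
    out$n_blocks <- vapply(strains, function(s)
      sum(blocks$strain == s), numeric(1), USE.NAMES = FALSE)
    out$mean_block_genes <- vapply(strains, function(s) {
      b <- blocks$n_genes[blocks$strain == s]
      if (length(b)) mean(b) else NA_real_
    }, numeric(1), USE.NAMES = FALSE)
  }
  out
}
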