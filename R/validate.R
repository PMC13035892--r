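#' Build the species panel used for block validation
#'
#' Mirrors the composition used for per-block phylogenies: two
#' S. cerevisiae representatives and five S. paradoxus representatives.
#' Panel member sequences are expressed over paradoxus-subgenome
#' coordinates: the paradoxus members are the paradoxus reference plus
#' donor-panel strains (their alternate alleles substituted in), and the
#' cerevisiae members are the cerevisiae reference (positionally aligned
#' ortholog) plus a lightly jittered second representative.
#'
#' @param parental Output of [simulate_parental_genomes()].
#' @param donor Output of [simulate_donor_panel()] (or `NULL` for a
#'   reference-only paradoxus side).
#' @param n_cer,n_par Panel members per species.
#' @param jitter_rate Substitution rate for extra same-species members.
#' @param seed Seed for the jittered members.
#' @return A list with `members` (tibble member/species) and `genomes`
#'   (named list of per-chromosome base vectors over `Spar_` contigs).
#' @export
build_validation_panel <- function(parental, donor = NULL, n_cer = 2,
                                   n_par = 5, jitter_rate = 0.005,
                                   seed = 99) {
  par_chroms <- grep("^Spar_", names(parental$genomes), value = TRUE)
  genomes <- list()
  members <- list()
  par_ref <- parental$genomes[par_chroms]
  cer_ref <- parental$genomes[sub("^Spar_", "Scer_", par_chroms)]
  names(cer_ref) <- par_chroms

  add_member <- function(name, species, gen) {
    members[[length(members) + 1]] <<- tibble::tibble(member = name,
                                                      species = species)
    genomes[[name]] <<- gen
  }
  jitter <- function(gen, rate) {
    lapply(gen, function(v) {
      mut <- which(stats::runif(length(v)) < rate)
      if (length(mut)) v[mut] <- mutate_bases(v[mut])
      v
    })
  }
  with_seed(seed, {
    add_member("cer_ref", "cerevisiae", cer_ref)
    if (n_cer > 1) for (k in 2:n_cer)
      add_member(paste0("cer_alt", k - 1), "cerevisiae",
                 jitter(cer_ref, jitter_rate))
    add_member("par_ref", "paradoxus", par_ref)
    donors <- if (!is.null(donor)) donor$lineages$strain else character(0)
    extra <- min(n_par - 1, length(donors))
    if (extra > 0) {
      # spread donor members across lineages for a representative panel
      pick <- donors[round(seq(1, length(donors), length.out = extra))]
      for (ds in pick)
        add_member(ds, "paradoxus", apply_variants(par_ref, donor$gm, ds))
    }
    if (n_par - 1 - extra > 0) for (k in seq_len(n_par - 1 - extra))
      add_member(paste0("par_alt", k), "paradoxus",
                 jitter(par_ref, jitter_rate))
  })
  list(members = do.call(rbind, members), genomes = genomes)
}

# substitute a strain's alternate alleles into a reference genome copy
apply_variants <- function(ref, gm, strain) {
  out <- ref
  alt <- which(gm$gt[, strain] >= 1L)
  if (length(alt)) {
    ch <- gm$sites$chrom[alt]
    for (cn in unique(ch)) {
      ii <- alt[ch == cn]
      out[[cn]][gm$sites$pos[ii]] <- gm$sites$alt[ii]
    }
  }
  out
}

#' Extract a focal strain's haplotype over a block's variant sites
#'
#' At sites inside the block's genes, the strain's allele is the alternate
#' allele whenever its genotype carries it (for heterozygous calls the
#' non-reference, paradoxus-subgenome alternate is taken) and the
#' reference allele otherwise; missing genotypes yield `NA`.
#'
#' @param gm Focal [genotype_matrix()].
#' @param strain Strain identifier.
#' @param block One row of a block table (list-column `gene_ids`).
#' @param annotation Annotation tibble.
#' @return A list with `pos` (site rows of `gm`) and `allele` (character).
#' @export
extract_block_haplotype <- function(gm, strain, block, annotation) {
  idx <- block_site_index(gm, block, annotation)
  g <- gm$gt[idx, strain]
  allele <- ifelse(is.na(g), NA_character_,
                   ifelse(g >= 1L, gm$sites$alt[idx], gm$sites$ref[idx]))
  list(site_index = idx, pos = gm$sites$pos[idx],
       chrom = gm$sites$chrom[idx], allele = allele)
}

block_site_index <- function(gm, block, annotation) {
  genes <- annotation[match(block$gene_ids[[1]], annotation$gene_id), ]
  hits <- logical(nrow(gm$sites))
  for (g in seq_len(nrow(genes))) {
    hits <- hits | (gm$sites$chrom == genes$chrom[g] &
                      gm$sites$pos >= genes$start[g] &
                      gm$sites$pos <= genes$end[g])
  }
  which(hits)
}

#' Align a focal block against the validation panel
#'
#' Builds a character alignment over the block's gene positions: one row
#' for the focal haplotype (paradoxus reference backbone with the strain's
#' alternate alleles substituted, `NA` at missing sites) and one row per
#' panel member. Invariant columns are removed.
#'
#' @param gm Focal [genotype_matrix()].
#' @param strain Strain identifier.
#' @param block One row of a block table.
#' @param annotation Annotation tibble.
#' @param panel Panel from [build_validation_panel()].
#' @return Character matrix (rows `focal` + panel members) or `NULL` when
#'   no variable column exists.
#' @export
block_alignment <- function(gm, strain, block, annotation, panel) {
  genes <- annotation[match(block$gene_ids[[1]], annotation$gene_id), ]
  cols <- list()
  for (g in seq_len(nrow(genes))) {
    cn <- genes$chrom[g]
    rng <- genes$start[g]:genes$end[g]
    base_rows <- vapply(panel$genomes, function(gen) gen[[cn]][rng],
                        character(length(rng)))
    focal <- panel$genomes[["par_ref"]][[cn]][rng]
    si <- which(gm$sites$chrom == cn & gm$sites$pos >= genes$start[g] &
                  gm$sites$pos <= genes$end[g])
    if (length(si)) {
      rel <- gm$sites$pos[si] - genes$start[g] + 1L
      gsub_ <- gm$gt[si, strain]
      focal[rel] <- ifelse(is.na(gsub_), NA_character_,
                           ifelse(gsub_ >= 1L, gm$sites$alt[si],
                                  gm$sites$ref[si]))
    }
    cols[[g]] <- cbind(focal = focal, base_rows)
  }
  aln <- t(do.call(rbind, cols))
  variable <- apply(aln, 2, function(col) {
    u <- unique(col[!is.na(col)])
    length(u) >= 2
  })
  if (!any(variable)) return(NULL)
  aln[, variable, drop = FALSE]
}

#' Pairwise p-distance matrix with pairwise deletion
#'
#' @param aln Character matrix, rows = sequences, columns = sites; `NA`
#'   cells are deleted pairwise.
#' @return Symmetric numeric matrix with zero diagonal.
#' @export
pdistance_matrix <- function(aln) {
  n <- nrow(aln)
  abort_if(n < 3, "pdistance_matrix: need at least 3 sequences")
  D <- matrix(0, n, n, dimnames = list(rownames(aln), rownames(aln)))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      ok <- !is.na(aln[i, ]) & !is.na(aln[j, ])
      abort_if(!any(ok), "pdistance_matrix: no overlapping sites between ",
               rownames(aln)[i], " and ", rownames(aln)[j])
      D[i, j] <- D[j, i] <- mean(aln[i, ok] != aln[j, ok])
    }
  }
  D
}

#' Decide whether a block groups with S. paradoxus
#'
#' Builds a neighbor-joining tree from the distance matrix and asks with
#' which species the focal haplotype attaches: the species of its nearest
#' panel member by patristic (tree-path) distance. Only blocks siding with
#' S. paradoxus are kept as true introgressions; a tie within `tol` is
#' indeterminate.
#'
#' @param D Distance matrix including a `focal` row (see
#'   [pdistance_matrix()]), or `NULL` for a zero-variant block.
#' @param species Named character vector mapping panel members to
#'   `"cerevisiae"` / `"paradoxus"`.
#' @param focal Name of the focal row.
#' @param tol Tie tolerance.
#' @return A list with `verdict` (`"validated"`, `"rejected"` or
#'   `"indeterminate"`), `nearest`, and the NJ `tree` (`phylo`).
#' @export
validate_block <- function(D, species, focal = "focal", tol = 1e-9) {
  if (is.null(D)) {
    return(list(verdict = "indeterminate", nearest = NA_character_,
                tree = NULL))
  }
  abort_if(!focal %in% rownames(D), "validate_block: no focal row")
  tree <- ape::nj(as.dist(D))
  pat <- stats::cophenetic(tree)
  d <- pat[focal, setdiff(colnames(pat), focal)]
  d_par <- min(d[names(d) %in% names(species)[species == "paradoxus"]])
  d_cer <- min(d[names(d) %in% names(species)[species == "cerevisiae"]])
  verdict <- if (abs(d_par - d_cer) <= tol) "indeterminate"
  else if (d_par < d_cer) "validated" else "rejected"
  list(verdict = verdict, nearest = names(d)[which.min(d)], tree = tree)
}

#' Validate every block of a call set against the species panel
#'
#' @param blocks Block table from [assemble_blocks()].
#' @param gm Focal [genotype_matrix()].
#' @param annotation Annotation tibble.
#' @param panel Panel from [build_validation_panel()].
#' @param tol Tie tolerance forwarded to [validate_block()].
#' @return `blocks` with a `validated` verdict column appended.
#' @export
validate_blocks <- function(blocks, gm, annotation, panel, tol = 1e-9) {
  species <- stats::setNames(panel$members$species, panel$members$member)
  verdicts <- character(nrow(blocks))
  for (b in seq_len(nrow(blocks))) {
    aln <- block_alignment(gm, blocks$strain[b], blocks[b, ], annotation,
                           panel)
    res <- validate_block(if (is.null(aln)) NULL else pdistance_matrix(aln),
                          species, tol = tol)
    verdicts[b] <- res$verdict
  }
  blocks$validated <- verdicts
  blocks
}
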