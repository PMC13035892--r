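#' Strain- and clade-level presence/absence of introgressed genes
#'
#' The strain matrix marks each gene present (1) wherever its call state is
#' not absent; the clade matrix holds, per clade and gene, the exact
#' fraction of carrier strains; the clade gene sets apply the carrier
#' threshold (default: at least one carrier strain).
#'
#' @param calls Call table from [call_introgressed_genes()].
#' @param roster Strain/clade tibble.
#' @param min_carriers Minimum carrier strains for clade-level presence.
#' @return A list with `strain_matrix` (binary, strains x genes),
#'   `clade_fractions` (clades x genes), `clade_sets` (named list of gene
#'   sets) and `clade_sizes`. Empty clades are excluded with a warning.
#' @export
build_presence_matrices <- function(calls, roster, min_carriers = 1) {
  present <- calls[calls$state != "absent", ]
  genes <- sort(unique(present$gene_id))
  strains <- unique(roster$strain)
  sm <- matrix(0L, length(strains), length(genes),
               dimnames = list(strains, genes))
  if (nrow(present) > 0)
    sm[cbind(match(present$strain, strains),
             match(present$gene_id, genes))] <- 1L
  clades <- unique(roster$clade)
  sizes <- vapply(clades, function(cl)
    sum(roster$clade == cl), integer(1))
  empty <- sizes == 0
  if (any(empty)) {
    warning("build_presence_matrices: excluding empty clade(s): ",
            paste(clades[empty], collapse = ", "), call. = FALSE)
    clades <- clades[!empty]; sizes <- sizes[!empty]
  }
  cf <- matrix(0, length(clades), length(genes),
               dimnames = list(clades, genes))
  carriers <- cf
  for (cl in clades) {
    rows <- roster$strain[roster$clade == cl]
    carriers[cl, ] <- colSums(sm[rows, , drop = FALSE])
    cf[cl, ] <- carriers[cl, ] / sizes[match(cl, clades)]
  }
  sets <- lapply(clades, function(cl)
    genes[carriers[cl, ] >= min_carriers])
  names(sets) <- clades
  list(strain_matrix = sm, clade_fractions = cf, clade_sets = sets,
       clade_sizes = stats::setNames(sizes, clades))
}

#' One-sided hypergeometric overlap test between two gene sets
#'
#' Upper-tail probability of observing an intersection at least as large
#' as the one seen, under random draws of two same-size sets from a common
#' universe (exact tail sum).
#'
#' @param set_a,set_b Character vectors of gene identifiers.
#' @param universe_size Size of the gene universe both sets come from.
#' @return One-row tibble: set sizes, observed intersection, `p_value`,
#'   `method = "hypergeometric"`.
#' @export
pairwise_overlap_test <- function(set_a, set_b, universe_size) {
  a <- length(unique(set_a)); b <- length(unique(set_b))
  obs <- length(intersect(set_a, set_b))
  abort_if(a > universe_size || b > universe_size,
           "pairwise_overlap_test: sets exceed the universe")
  stopifnot(obs <= min(a, b))
  p <- stats::phyper(obs - 1, a, universe_size - a, b, lower.tail = FALSE)
  tibble::tibble(n_a = a, n_b = b, universe = universe_size,
                 observed = obs, p_value = p, method = "hypergeometric")
}

#' Genes shared by every clade
#'
#' @param sets Named list of at least two gene sets.
#' @return A list with `genes` (the exact intersection) and `count`.
#' @export
multiway_shared_genes <- function(sets) {
  abort_if(length(sets) < 2, "multiway_shared_genes: need >= 2 sets")
  genes <- Reduce(intersect, sets)
  list(genes = genes, count = length(genes))
}

#' Significance of a multi-way gene-set intersection
#'
#' Null model: each set is an independent uniform draw of its own size
#' from the universe. `method = "permutation"` draws such sets and uses the
#' add-one permutation p-value `(hits + 1) / (n_perm + 1)`;
#' `method = "exact"` computes the exact tail by chaining hypergeometric
#' distributions (the intersection after each additional independent set
#' is hypergeometric given the running intersection size).
#'
#' @param sets Named list of gene sets.
#' @param universe_size Universe size.
#' @param n_perm Permutation count.
#' @param seed RNG seed for the permutation route.
#' @param method `"permutation"` or `"exact"`.
#' @return One-row tibble with the observed intersection and `p_value`.
#' @export
multiway_overlap_pvalue <- function(sets, universe_size, n_perm = 1e5,
                                    seed = 1, method = c("permutation",
                                                         "exact")) {
  method <- match.arg(method)
  abort_if(universe_size < max(lengths(sets)),
           "multiway_overlap_pvalue: universe smaller than a set")
  obs <- multiway_shared_genes(sets)$count
  sizes <- lengths(sets)
  if (method == "permutation") {
    hits <- with_seed(seed, {
      sum(vapply(seq_len(n_perm), function(i) {
        inter <- sample.int(universe_size, sizes[1])
        for (k in 2:length(sizes)) {
          if (length(inter) == 0) break
          inter <- intersect(inter, sample.int(universe_size, sizes[k]))
        }
        length(inter) >= obs
      }, logical(1)))
    })
    p <- (hits + 1) / (n_perm + 1)
  } else {
    # P(I_k = m): chain I_1 = |S_1|; I_j | I_{j-1} ~ Hypergeom
    dist <- c(rep(0, sizes[1]), 1)  # point mass at |S_1|; index m+1
    for (k in 2:length(sizes)) {
      new <- rep(0, sizes[1] + 1)
      for (m in which(dist > 0) - 1) {
        mm <- 0:m
        new[mm + 1] <- new[mm + 1] + dist[m + 1] *
          stats::dhyper(mm, m, universe_size - m, sizes[k])
      }
      dist <- new
    }
    # guard against underflow for extreme cores; p is never exactly 0
    p <- max(sum(dist[(obs + 1):length(dist)]), .Machine$double.xmin)
  }
  tibble::tibble(n_sets = length(sets), universe = universe_size,
                 observed = obs, p_value = p, method = method,
                 n_perm = if (method == "permutation") n_perm else NA_integer_)
}

#' Cluster clades by their introgressed-gene retention profiles
#'
#' Agglomerative clustering (average linkage) on Euclidean distances
#' between clade rows of the carrier-fraction matrix. Rows are sorted by
#' clade name first so that tied merges resolve deterministically.
#'
#' @param clade_fractions Clade x gene fraction matrix from
#'   [build_presence_matrices()].
#' @return A list with `hclust`, `leaf_order` (clade names) and `newick`.
#' @export
cluster_retention_patterns <- function(clade_fractions) {
  abort_if(nrow(clade_fractions) < 2,
           "cluster_retention_patterns: need >= 2 clades")
  m <- clade_fractions[order(rownames(clade_fractions)), , drop = FALSE]
  hc <- stats::hclust(stats::dist(m, method = "euclidean"),
                      method = "average")
  phy <- ape::as.phylo(hc)
  list(hclust = hc, leaf_order = hc$labels[hc$order],
       newick = ape::write.tree(phy))
}
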