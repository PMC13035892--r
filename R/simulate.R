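DNA_BASES <- c("A", "C", "G", "T")

mutate_bases <- function(base) {
  # substitute each base with one of the three alternatives, uniformly
  idx <- match(base, DNA_BASES)
  shift <- sample.int(3L, length(base), replace = TRUE)
  DNA_BASES[((idx + shift - 1L) %% 4L) + 1L]
}

chrom_name <- function(subgenome, i) {
  sprintf("%s_chr%02d", ifelse(subgenome == "cer", "Scer", "Spar"), i)
}

#' Simulate the two diverged parental subgenome references
#'
#' Generates an S. cerevisiae-like reference and an S. paradoxus-like
#' ortholog of it, diverged by point substitutions at the configured rate,
#' together with a gene annotation in which every paradoxus gene is paired
#' 1:1 with its cerevisiae ortholog and the realized per-ortholog divergence
#' is recorded.
#'
#' @param config A [sim_config()].
#' @return A list with `genomes` (named list of per-chromosome base
#'   vectors, contigs prefixed `Scer_`/`Spar_`), `annotation` (tibble, one
#'   row per gene of each subgenome) and `config`.
#' @export
simulate_parental_genomes <- function(config) {
  validate_sim_config(config)
  abort_if(config$gene_length < 1, "gene_length must be positive")
  abort_if(config$intergenic_length < 1,
           "intergenic_length must be positive (adjacent genes may not overlap)")
  with_seed(config$seed, {
    genomes <- list()
    ann <- vector("list", config$n_chromosomes)
    gl <- config$gene_length
    il <- config$intergenic_length
    ng <- config$genes_per_chromosome
    chrom_len <- ng * (gl + il) + il
    for (ci in seq_len(config$n_chromosomes)) {
      cer <- sample(DNA_BASES, chrom_len, replace = TRUE)
      mut <- which(stats::runif(chrom_len) < config$parental_divergence)
      par <- cer
      if (length(mut) > 0) par[mut] <- mutate_bases(cer[mut])
      genomes[[chrom_name("cer", ci)]] <- cer
      genomes[[chrom_name("par", ci)]] <- par
      starts <- il + (seq_len(ng) - 1L) * (gl + il) + 1L
      ends <- starts + gl - 1L
      ndiff <- vapply(seq_len(ng), function(g) {
        sum(cer[starts[g]:ends[g]] != par[starts[g]:ends[g]])
      }, integer(1))
      cer_ids <- sprintf("cer_%02d_%03d", ci, seq_len(ng))
      par_ids <- sprintf("par_%02d_%03d", ci, seq_len(ng))
      ann[[ci]] <- tibble::tibble(
        gene_id = c(cer_ids, par_ids),
        subgenome = rep(c("cer", "par"), each = ng),
        chrom = rep(c(chrom_name("cer", ci), chrom_name("par", ci)), each = ng),
        start = rep(starts, 2), end = rep(ends, 2),
        order_index = rep(seq_len(ng), 2),
        ortholog_id = c(par_ids, cer_ids),
        ortholog_divergence = rep(ndiff / gl, 2),
        n_diff_sites = rep(ndiff, 2)
      )
    }
    list(genomes = genomes, annotation = do.call(rbind, ann), config = config)
  })
}

#' Genome-wide realized divergence between the two parental references
#' @param parental Output of [simulate_parental_genomes()].
#' @return Fraction of differing sites.
#' @export
realized_divergence <- function(parental) {
  cer <- grep("^Scer_", names(parental$genomes), value = TRUE)
  diff <- 0L; tot <- 0L
  for (cn in cer) {
    pn <- sub("^Scer_", "Spar_", cn)
    diff <- diff + sum(parental$genomes[[cn]] != parental$genomes[[pn]])
    tot <- tot + length(parental$genomes[[cn]])
  }
  diff / tot
}

#' Simulate a labeled S. paradoxus donor panel
#'
#' Each donor lineage carries private variants at the configured rate on
#' top of panel-wide shared variation; individual panel strains add a small
#' amount of within-lineage variation. Lineage-private variation is what
#' makes maximum-IBS donor assignment identifiable.
#'
#' @param config A [sim_config()]; requires `n_donor_lineages >= 2` and
#'   `donor_private_divergence > 0`.
#' @param parental Output of [simulate_parental_genomes()].
#' @return A list with `gm` (a [genotype_matrix()] of panel genotypes on
#'   the paradoxus subgenome) and `lineages` (tibble strain/lineage).
#' @export
simulate_donor_panel <- function(config, parental) {
  abort_if(config$n_donor_lineages < 2,
           "simulate_donor_panel: at least 2 donor lineages are required")
  abort_if(config$donor_private_divergence == 0,
           "simulate_donor_panel: donor_private_divergence = 0 makes donor ",
           "origin assignment unidentifiable; use a positive rate")
  with_seed(config$seed + 1L, {
    lineage_names <- paste0("Sp", LETTERS[seq_len(config$n_donor_lineages)])
    strains <- unlist(lapply(lineage_names, function(l)
      sprintf("%s_d%02d", l, seq_len(config$donors_per_lineage))))
    lineages <- tibble::tibble(
      strain = strains,
      lineage = rep(lineage_names, each = config$donors_per_lineage))
    par_chroms <- grep("^Spar_", names(parental$genomes), value = TRUE)
    site_list <- list()
    for (cn in par_chroms) {
      L <- length(parental$genomes[[cn]])
      pos_priv <- lapply(lineage_names, function(l)
        which(stats::runif(L) < config$donor_private_divergence))
      pos_shared <- which(stats::runif(L) < config$donor_shared_divergence)
      pos_noise <- lapply(strains, function(s)
        which(stats::runif(L) < config$donor_within_noise))
      pos <- c(unlist(pos_priv), pos_shared, unlist(pos_noise))
      class_lab <- c(rep(lineage_names, lengths(pos_priv)),
                     rep(".shared", length(pos_shared)),
                     rep(strains, lengths(pos_noise)))
      keep <- !duplicated(pos)
      pos <- pos[keep]; class_lab <- class_lab[keep]
      ord <- order(pos)
      pos <- pos[ord]; class_lab <- class_lab[ord]
      if (length(pos) == 0) next
      ref <- parental$genomes[[cn]][pos]
      alt <- mutate_bases(ref)
      gt <- matrix(0L, nrow = length(pos), ncol = length(strains),
                   dimnames = list(NULL, strains))
      for (i in seq_along(pos)) {
        cl <- class_lab[i]
        if (cl == ".shared") {
          f <- stats::runif(1, 0.1, 0.9)
          gt[i, stats::runif(length(strains)) < f] <- 2L
        } else if (cl %in% lineage_names) {
          gt[i, lineages$lineage == cl] <- 2L
        } else {
          gt[i, strains == cl] <- 2L
        }
      }
      site_list[[cn]] <- list(
        sites = tibble::tibble(chrom = cn, pos = pos, ref = ref, alt = alt,
                               qual = 1000),
        gt = gt)
    }
    sites <- do.call(rbind, lapply(site_list, `[[`, "sites"))
    gt <- do.call(rbind, lapply(site_list, `[[`, "gt"))
    dp <- matrix(100, nrow = nrow(gt), ncol = ncol(gt),
                 dimnames = dimnames(gt))
    list(gm = genotype_matrix(sites, gt, dp), lineages = lineages)
  })
}

#' Strain roster implied by a simulation config
#'
#' @param config A [sim_config()].
#' @return Tibble with `strain` and `clade`.
#' @export
strain_roster <- function(config) {
  clades <- sprintf("C%02d", seq_len(config$n_clades))
  tibble::tibble(
    strain = unlist(lapply(clades, function(cl)
      sprintf("%s_s%02d", cl, seq_len(config$strains_per_clade)))),
    clade = rep(clades, each = config$strains_per_clade))
}

#' Map clades to introgression pulses and donor lineages
#' @noRd
pulse_plan <- function(config, lineage_names) {
  clades <- sprintf("C%02d", seq_len(config$n_clades))
  pulse_of_clade <- ((seq_along(clades) - 1L) %% config$n_pulses) + 1L
  lineage_of_pulse <- lineage_names[((seq_len(config$n_pulses) - 1L) %%
                                       length(lineage_names)) + 1L]
  tibble::tibble(clade = clades,
                 pulse = pulse_of_clade,
                 lineage = lineage_of_pulse[pulse_of_clade])
}

#' Plant introgression blocks into focal strains
#'
#' Models introgression pulses: each pulse assigns one donor lineage to all
#' clades it targets (clades are distributed round-robin over pulses).
#' Every strain of a targeted clade receives the pulse's shared ancestral
#' block(s) plus a Poisson number of strain-private blocks; block lengths
#' are shifted-geometric in genes and each block is heterozygous with
#' probability `het_fraction`. Genotypes of introgressed regions are copied
#' from a donor panel strain of the pulse lineage into the focal genotype
#' matrix (heterozygous blocks carry the donor allele on one haplotype).
#'
#' @param config A [sim_config()].
#' @param annotation Annotation tibble from [simulate_parental_genomes()].
#' @param donor Output of [simulate_donor_panel()].
#' @return A list with `truth` (per strain x paradoxus gene state table),
#'   `truth_blocks` (maximal runs of introgressed genes with donor lineage
#'   and zygosity), and `focal_gm` (focal genotypes at panel sites;
#'   missing outside introgressed regions, as competitive mapping yields no
#'   paradoxus-subgenome coverage there).
#' @export
plant_introgressions <- function(config, annotation, donor) {
  roster <- strain_roster(config)
  lineage_names <- unique(donor$lineages$lineage)
  plan <- pulse_plan(config, lineage_names)
  par_ann <- annotation[annotation$subgenome == "par", ]
  par_ann <- par_ann[order(par_ann$chrom, par_ann$order_index), ]
  ng <- config$genes_per_chromosome
  chroms <- unique(par_ann$chrom)
  geom_p <- 1 / config$block_length_mean

  with_seed(config$seed + 2L, {
    draw_block <- function() {
      len <- 1L + stats::rgeom(1L, geom_p)
      len <- min(len, ng)
      chrom <- sample(chroms, 1L)
      start <- sample.int(ng - len + 1L, 1L)
      list(chrom = chrom, idx = start:(start + len - 1L),
           het = stats::runif(1) < config$het_fraction)
    }
    # state/donor matrices: strains x (chrom, order) flattened by gene row
    n_par <- nrow(par_ann)
    gene_key <- paste(par_ann$chrom, par_ann$order_index)
    state <- matrix("absent", nrow = n_par, ncol = nrow(roster),
                    dimnames = list(par_ann$gene_id, roster$strain))
    donor_of <- matrix(NA_character_, n_par, nrow(roster),
                       dimnames = dimnames(state))
    lineage_of <- donor_of

    apply_block <- function(blk, strain, lineage, donor_strain) {
      rows <- match(paste(blk$chrom, blk$idx), gene_key)
      fresh <- rows[state[rows, strain] == "absent"]
      if (length(fresh) == 0) return(invisible(NULL))
      state[fresh, strain] <<- if (blk$het) "introgressed_het" else "introgressed_hom"
      donor_of[fresh, strain] <<- donor_strain
      lineage_of[fresh, strain] <<- lineage
      invisible(NULL)
    }

    if (config$block_rate > 0 || config$shared_blocks_per_pulse > 0) {
      for (p in seq_len(config$n_pulses)) {
        p_clades <- plan$clade[plan$pulse == p]
        lineage <- plan$lineage[plan$pulse == p][1]
        lin_strains <- donor$lineages$strain[donor$lineages$lineage == lineage]
        if (config$block_rate > 0 && config$shared_blocks_per_pulse > 0) {
          for (b in seq_len(config$shared_blocks_per_pulse)) {
            blk <- draw_block()
            ds <- sample(lin_strains, 1L)
            for (s in roster$strain[roster$clade %in% p_clades])
              apply_block(blk, s, lineage, ds)
          }
        }
        if (config$block_rate > 0) {
          for (s in roster$strain[roster$clade %in% p_clades]) {
            nb <- stats::rpois(1L, config$block_rate)
            if (nb > 0) for (b in seq_len(nb)) {
              blk <- draw_block()
              apply_block(blk, s, lineage, sample(lin_strains, 1L))
            }
          }
        }
      }
    }

    truth <- tibble::tibble(
      strain = rep(roster$strain, each = n_par),
      clade = rep(roster$clade, each = n_par),
      gene_id = rep(par_ann$gene_id, nrow(roster)),
      chrom = rep(par_ann$chrom, nrow(roster)),
      order_index = rep(par_ann$order_index, nrow(roster)),
      state = as.vector(state),
      donor_lineage = as.vector(lineage_of),
      donor_strain = as.vector(donor_of))

    truth_blocks <- derive_truth_blocks(truth)

    # focal genotypes at panel sites: copied from the gene's donor strain
    site_gene <- site_gene_index(donor$gm$sites, par_ann)
    n_sites <- nrow(donor$gm$sites)
    gt <- matrix(NA_integer_, n_sites, nrow(roster),
                 dimnames = list(NULL, roster$strain))
    dp <- matrix(0, n_sites, nrow(roster), dimnames = dimnames(gt))
    sites_of_gene <- split(seq_len(n_sites), site_gene)
    intro <- truth[truth$state != "absent", ]
    if (nrow(intro) > 0) {
      for (i in seq_len(nrow(intro))) {
        idx <- sites_of_gene[[intro$gene_id[i]]]
        if (is.null(idx)) next
        d <- donor$gm$gt[idx, intro$donor_strain[i]]
        if (intro$state[i] == "introgressed_het") {
          gt[idx, intro$strain[i]] <- pmin(d, 1L)
          dp[idx, intro$strain[i]] <- config$mean_depth / 2
        } else {
          gt[idx, intro$strain[i]] <- d
          dp[idx, intro$strain[i]] <- config$mean_depth
        }
      }
    }
    focal_gm <- genotype_matrix(donor$gm$sites, gt, dp)
    list(truth = truth, truth_blocks = truth_blocks, focal_gm = focal_gm)
  })
}

# index of the annotated gene covering each site (NA when intergenic)
site_gene_index <- function(sites, ann) {
  out <- rep(NA_character_, nrow(sites))
  for (cn in unique(sites$chrom)) {
    a <- ann[ann$chrom == cn, ]
    if (nrow(a) == 0) next
    si <- which(sites$chrom == cn)
    g <- findInterval(sites$pos[si], a$start)
    ok <- g >= 1 & g <= nrow(a)
    ok[ok] <- sites$pos[si][ok] <= a$end[g[ok]]
    out[si[ok]] <- a$gene_id[g[ok]]
  }
  out
}

# maximal runs of introgressed genes per strain/chromosome; donor lineage
# of a run is its modal gene-level lineage (unique under the default
# one-pulse-per-clade plan)
derive_truth_blocks <- function(truth) {
  intro <- truth[truth$state != "absent", ]
  if (nrow(intro) == 0) {
    return(tibble::tibble(block_id = character(0), strain = character(0),
                          chrom = character(0), first_index = integer(0),
                          n_genes = integer(0), gene_ids = list(),
                          donor_lineage = character(0), any_het = logical(0)))
  }
  intro <- intro[order(intro$strain, intro$chrom, intro$order_index), ]
  new_run <- c(TRUE, intro$strain[-1] != intro$strain[-nrow(intro)] |
                 intro$chrom[-1] != intro$chrom[-nrow(intro)] |
                 diff(intro$order_index) != 1L)
  run <- cumsum(new_run)
  parts <- split(seq_len(nrow(intro)), run)
  rows <- lapply(parts, function(ii) {
    x <- intro[ii, ]
    lin <- names(sort(table(x$donor_lineage), decreasing = TRUE))[1]
    tibble::tibble(strain = x$strain[1], chrom = x$chrom[1],
                   first_index = x$order_index[1],
                   n_genes = nrow(x), gene_ids = list(x$gene_id),
                   donor_lineage = lin,
                   any_het = any(x$state == "introgressed_het"))
  })
  out <- do.call(rbind, rows)
  out$block_id <- sprintf("%s:%s:%d", out$strain, out$chrom, out$first_index)
  out[, c("block_id", "strain", "chrom", "first_index", "n_genes",
          "gene_ids", "donor_lineage", "any_het")]
}

#' Simulate per-gene competitive-mapping depth summaries
#'
#' Encodes the coverage signature of competitive mapping: a paradoxus gene
#' receives full depth when homozygously introgressed, half depth when
#' heterozygous and none otherwise; the cerevisiae ortholog loses exactly
#' the depth the paradoxus copy gains. The `poisson` model draws the
#' per-gene mean from a Poisson law over gene positions and the covered
#' fraction from the implied per-position exceedance probability.
#'
#' @param config A [sim_config()].
#' @param truth Truth table from [plant_introgressions()].
#' @param annotation Annotation tibble.
#' @return Tibble with `strain`, `gene_id`, `subgenome`,
#'   `frac_above_threshold`, `gene_depth`, `strain_median`.
#' @export
simulate_depths <- function(config, truth, annotation) {
  strains <- unique(truth$strain)
  ann <- annotation[order(annotation$chrom, annotation$order_index), ]
  n_gene <- nrow(ann)
  gl <- config$gene_length
  state_of <- matrix("absent", nrow = n_gene, ncol = length(strains),
                     dimnames = list(ann$gene_id, strains))
  intro <- truth[truth$state != "absent", ]
  if (nrow(intro) > 0)
    state_of[cbind(match(intro$gene_id, ann$gene_id),
                   match(intro$strain, strains))] <- intro$state
  # cerevisiae genes inherit the mirrored state of their paradoxus ortholog
  is_cer <- ann$subgenome == "cer"
  ortho_row <- match(ann$ortholog_id, ann$gene_id)
  cer_state <- state_of[ortho_row[is_cer], , drop = FALSE]

  expected <- matrix(0, n_gene, length(strains),
                     dimnames = dimnames(state_of))
  md <- config$mean_depth
  par_state <- state_of[!is_cer, , drop = FALSE]
  expected[!is_cer, ][par_state == "introgressed_hom"] <- md
  expected[!is_cer, ][par_state == "introgressed_het"] <- md / 2
  ec <- matrix(md, sum(is_cer), length(strains))
  ec[cer_state == "introgressed_hom"] <- 0
  ec[cer_state == "introgressed_het"] <- md / 2
  expected[is_cer, ] <- ec

  with_seed(config$seed + 3L, {
    if (config$depth_model == "noiseless") {
      strain_median <- md
      thr <- 0.25 * strain_median
      gene_depth <- expected
      frac <- (expected > thr) * 1
    } else {
      strain_median <- stats::qpois(0.5, md)
      thr <- 0.25 * strain_median
      e <- as.vector(expected)
      gene_depth <- matrix(stats::rpois(length(e), e * gl) / gl,
                           n_gene, length(strains))
      p_above <- stats::ppois(floor(thr), e, lower.tail = FALSE)
      frac <- matrix(stats::rbinom(length(e), gl, p_above) / gl,
                     n_gene, length(strains))
    }
    tibble::tibble(
      strain = rep(strains, each = n_gene),
      gene_id = rep(ann$gene_id, length(strains)),
      subgenome = rep(ann$subgenome, length(strains)),
      frac_above_threshold = as.vector(frac),
      gene_depth = as.vector(gene_depth),
      strain_median = strain_median)
  })
}

#' Simulate per-position depth profiles for selected strains
#'
#' Per-position counterpart of [simulate_depths()], intended for
#' integration-testing the gene-level summarizer on small genomes.
#' Intergenic positions carry full depth on the resident subgenome and
#' none on the paradoxus subgenome.
#'
#' @inheritParams simulate_depths
#' @param strains Strains to emit (defaults to all in `truth`).
#' @return Tibble with `strain`, `chrom`, `pos`, `depth`.
#' @export
simulate_position_depths <- function(config, truth, annotation,
                                     strains = NULL) {
  strains <- strains %||% unique(truth$strain)
  chrom_len <- config$genes_per_chromosome *
    (config$gene_length + config$intergenic_length) + config$intergenic_length
  md <- config$mean_depth
  out <- list()
  with_seed(config$seed + 6L, {
    for (s in strains) {
      tt <- truth[truth$strain == s & truth$state != "absent", ]
      for (sub in c("cer", "par")) {
        for (ci in seq_len(config$n_chromosomes)) {
          cn <- chrom_name(sub, ci)
          e <- rep(if (sub == "cer") md else 0, chrom_len)
          ann_c <- annotation[annotation$chrom == cn, ]
          for (g in seq_len(nrow(ann_c))) {
            gid <- ann_c$gene_id[g]
            rng <- ann_c$start[g]:ann_c$end[g]
            if (sub == "par") {
              st <- tt$state[tt$gene_id == gid]
              if (length(st) == 1)
                e[rng] <- if (st == "introgressed_hom") md else md / 2
            } else {
              ortho <- ann_c$ortholog_id[g]
              st <- tt$state[tt$gene_id == ortho]
              if (length(st) == 1)
                e[rng] <- if (st == "introgressed_hom") 0 else md / 2
            }
          }
          depth <- if (config$depth_model == "poisson")
            stats::rpois(chrom_len, e) else e
          out[[paste(s, cn)]] <- tibble::tibble(
            strain = s, chrom = cn, pos = seq_len(chrom_len), depth = depth)
        }
      }
    }
  })
  do.call(rbind, out)
}

#' Simulate clade-structured geography with isolation by distance
#'
#' Places clade centroids along a geographic transect and scatters strains
#' around their clade centroid. With `ibd_strength > 0` the background
#' allele-frequency model ties genetic differentiation to the same
#' transect, producing a positive geography-genetics (Mantel) correlation.
#'
#' @param config A [sim_config()].
#' @param roster Tibble with `strain` and `clade` (see [strain_roster()]).
#' @return Tibble with `strain`, `clade`, `lon`, `lat`; clade centroids are
#'   attached as attribute `"centroids"`.
#' @export
simulate_geography <- function(config, roster) {
  abort_if(config$ibd_strength < 0, "ibd_strength must be >= 0")
  clades <- unique(roster$clade)
  centroids <- tibble::tibble(
    clade = clades,
    lon = -106 + 1.6 * (seq_along(clades) - 1L),
    lat = 25 - 2.2 * (seq_along(clades) - 1L))
  with_seed(config$seed + 4L, {
    i <- match(roster$clade, clades)
    coords <- tibble::tibble(
      strain = roster$strain, clade = roster$clade,
      lon = centroids$lon[i] + stats::rnorm(nrow(roster), 0, config$geo_jitter_sd),
      lat = centroids$lat[i] + stats::rnorm(nrow(roster), 0, config$geo_jitter_sd))
    attr(coords, "centroids") <- centroids
    coords
  })
}

#' Simulate background SNPs on the resident subgenome
#'
#' Clade-structured biallelic variation on the cerevisiae subgenome: each
#' site has an ancestral frequency, a geographic-gradient effect scaled by
#' `ibd_strength`, and clade-level drift; strain genotypes are drawn under
#' Hardy-Weinberg within clades. This is the substrate for the population
#' structure, diversity and isolation-by-distance statistics.
#'
#' @param config A [sim_config()].
#' @param annotation Annotation tibble (defines chromosome extents).
#' @param roster Strain/clade tibble.
#' @param geography Output of [simulate_geography()].
#' @return A [genotype_matrix()] on `Scer_` contigs.
#' @export
simulate_background_snps <- function(config, annotation, roster, geography) {
  centroids <- attr(geography, "centroids")
  clades <- centroids$clade
  z <- as.vector(scale(centroids$lat))
  if (any(!is.finite(z))) z <- rep(0, length(z))
  chrom_len <- config$genes_per_chromosome *
    (config$gene_length + config$intergenic_length) + config$intergenic_length
  with_seed(config$seed + 5L, {
    site_list <- list()
    for (ci in seq_len(config$n_chromosomes)) {
      cn <- chrom_name("cer", ci)
      pos <- which(stats::runif(chrom_len) < config$background_site_rate)
      if (length(pos) == 0) next
      n <- length(pos)
      p0 <- stats::runif(n, 0.05, 0.95)
      slope <- stats::rnorm(n, 0, config$ibd_strength)
      drift <- matrix(stats::rnorm(n * length(clades), 0, config$clade_drift_sd),
                      n, length(clades))
      pc <- stats::plogis(stats::qlogis(p0) + outer(slope, z) + drift)
      ii <- match(roster$clade, clades)
      gt <- matrix(stats::rbinom(n * nrow(roster), 2L, pc[, ii]),
                   n, nrow(roster), dimnames = list(NULL, roster$strain))
      miss <- matrix(stats::runif(n * nrow(roster)) < config$background_missing_rate,
                     n, nrow(roster))
      gt[miss] <- NA_integer_
      ref <- sample(DNA_BASES, n, replace = TRUE)
      site_list[[cn]] <- list(
        sites = tibble::tibble(chrom = cn, pos = pos, ref = ref,
                               alt = mutate_bases(ref),
                               qual = round(stats::runif(n, 500, 5000))),
        gt = gt)
    }
    sites <- do.call(rbind, lapply(site_list, `[[`, "sites"))
    gt <- do.call(rbind, lapply(site_list, `[[`, "gt"))
    dp <- matrix(config$mean_depth, nrow(gt), ncol(gt), dimnames = dimnames(gt))
    if (config$depth_model == "poisson")
      dp[] <- stats::rpois(length(dp), config$mean_depth)
    genotype_matrix(sites, gt, dp)
  })
}

#' Generate a complete synthetic dataset with recorded ground truth
#'
#' Runs the whole generator: parental references and annotation, donor
#' panel, strain roster and geography, planted introgressions, background
#' variation, combined focal genotype matrix (both subgenomes) and per-gene
#' depth summaries. All randomness derives from `config$seed`; identical
#' configs yield identical datasets.
#'
#' @param config A [sim_config()].
#' @param out_dir Optional directory; when given, all standard files
#'   (FASTA, GFF3, VCFs, TSVs and a manifest JSON) are written there via
#'   [write_dataset()].
#' @return A list bundle with all components and ground truth.
#' @export
simulate_dataset <- function(config, out_dir = NULL) {
  parental <- simulate_parental_genomes(config)
  donor <- simulate_donor_panel(config, parental)
  roster <- strain_roster(config)
  geography <- simulate_geography(config, roster)
  planted <- plant_introgressions(config, parental$annotation, donor)
  background <- simulate_background_snps(config, parental$annotation,
                                         roster, geography)
  focal_gm <- gm_rbind(background, planted$focal_gm)
  depths <- simulate_depths(config, planted$truth, parental$annotation)
  sim <- list(config = config, parental = parental, donor = donor,
              roster = roster, geography = geography,
              truth = planted$truth, truth_blocks = planted$truth_blocks,
              background_gm = background, focal_gm = focal_gm,
              depths = depths)
  class(sim) <- "introgressr_sim"
  if (!is.null(out_dir)) write_dataset(sim, out_dir)
  sim
}

#' Per-strain SNV counts against single-species vs concatenated references
#'
#' Mimics the consequence of the mapping strategy on variant counts: when
#' reads are mapped to the resident (cerevisiae-only) reference, reads from
#' introgressed segments pile up on the cerevisiae ortholog and every
#' fixed interspecies difference inside those genes surfaces as an apparent
#' SNV; under competitive mapping those reads settle on the paradoxus
#' subgenome and the resident subgenome stays clean.
#'
#' @param sim Output of [simulate_dataset()].
#' @return Tibble with per-strain `n_snv_single_ref` (cerevisiae-only
#'   reference, introgressions included) and `n_snv_competitive`
#'   (concatenated reference, resident subgenome only).
#' @export
snv_reference_counts <- function(sim) {
  bg <- sim$background_gm
  base <- colSums(bg$gt > 0, na.rm = TRUE)
  ann <- sim$parental$annotation
  ndiff <- stats::setNames(ann$n_diff_sites, ann$gene_id)
  intro <- sim$truth[sim$truth$state != "absent", ]
  extra <- vapply(names(base), function(s)
    sum(ndiff[intro$gene_id[intro$strain == s]]), numeric(1))
  tibble::tibble(strain = names(base),
                 n_snv_competitive = unname(base),
                 n_snv_single_ref = unname(base + extra))
}
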