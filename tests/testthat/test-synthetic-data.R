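test_that("parental genomes realize the configured divergence", {
  cfg <- sim_config(n_clades = 1, strains_per_clade = 1,
                    n_chromosomes = 8, genes_per_chromosome = 50,
                    gene_length = 1000, seed = 42)
  p <- simulate_parental_genomes(cfg)
  # independent recount straight off the sequences
  cer <- grep("^Scer_", names(p$genomes), value = TRUE)
  diff <- sum(vapply(cer, function(cn)
    sum(p$genomes[[cn]] != p$genomes[[sub("Scer", "Spar", cn)]]),
    numeric(1)))
  tot <- sum(vapply(cer, function(cn) length(p$genomes[[cn]]), numeric(1)))
  expect_equal(realized_divergence(p), diff / tot)
  expect_gt(diff / tot, 0.11)
  expect_lt(diff / tot, 0.13)

  # annotation's per-ortholog divergence equals recount from gene sequences
  par_ann <- p$annotation[p$annotation$subgenome == "par", ]
  pick <- par_ann[c(1, 57, 399), ]
  for (i in seq_len(nrow(pick))) {
    g <- pick[i, ]
    cer_chrom <- sub("Spar", "Scer", g$chrom)
    recount <- mean(p$genomes[[g$chrom]][g$start:g$end] !=
                      p$genomes[[cer_chrom]][g$start:g$end])
    expect_equal(g$ortholog_divergence, recount)
  }
})

test_that("zero parental divergence yields identical orthologs", {
  cfg <- tiny_config(parental_divergence = 0)
  p <- simulate_parental_genomes(cfg)
  expect_true(all(p$annotation$ortholog_divergence == 0))
  # every gene then fails the 5% divergence rule
  sim <- simulate_dataset(cfg)
  calls <- call_introgressed_genes(sim$depths, p$annotation)
  expect_true(all(calls$state == "absent"))
})

test_that("same seed and config give byte-identical outputs", {
  cfg <- tiny_config()
  d1 <- file.path(tempdir(), "det1"); d2 <- file.path(tempdir(), "det2")
  simulate_dataset(cfg, out_dir = d1)
  simulate_dataset(cfg, out_dir = d2)
  f1 <- list.files(d1)
  expect_setequal(f1, list.files(d2))
  for (f in f1) {
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))),
                     label = paste("checksum of", f))
  }
  unlink(c(d1, d2), recursive = TRUE)
})

test_that("donor lineages are more similar within than between", {
  cfg <- tiny_config(n_donor_lineages = 2, donor_private_divergence = 0.02)
  p <- simulate_parental_genomes(cfg)
  donor <- simulate_donor_panel(cfg, p)
  ibs <- ibs_matrix(donor$gm)
  lin <- donor$lineages$lineage[match(rownames(ibs), donor$lineages$strain)]
  same <- outer(lin, lin, "==") & upper.tri(ibs)
  diff <- outer(lin, lin, "!=") & upper.tri(ibs)
  expect_gt(mean(ibs[same]), mean(ibs[diff]))
})

test_that("degenerate donor-panel configs are rejected", {
  cfg1 <- tiny_config(n_donor_lineages = 1)
  p <- simulate_parental_genomes(cfg1)
  expect_error(simulate_donor_panel(cfg1, p), "at least 2 donor lineages")
  cfg0 <- tiny_config(donor_private_divergence = 0)
  expect_error(simulate_donor_panel(cfg0, p), "unidentifiable")
})

test_that("planting respects block rate, pulses and zygosity settings", {
  cfg0 <- tiny_config(block_rate = 0)
  sim0 <- simulate_dataset(cfg0)
  expect_identical(sum(sim0$truth$state != "absent"), 0L)

  cfg1 <- tiny_config(het_fraction = 1)
  sim1 <- simulate_dataset(cfg1)
  intro <- sim1$truth[sim1$truth$state != "absent", ]
  expect_gt(nrow(intro), 0)
  expect_true(all(intro$state == "introgressed_het"))

  # one pulse: every planted gene carries the pulse's single lineage
  cfgp <- tiny_config(n_pulses = 1)
  simp <- simulate_dataset(cfgp)
  lin <- unique(na.omit(simp$truth$donor_lineage))
  expect_length(lin, 1)

  # block gene sets agree between the gene-level truth and truth blocks
  tb <- simp$truth_blocks
  expect_setequal(unlist(tb$gene_ids),
                  simp$truth$gene_id[simp$truth$state != "absent" &
                                       simp$truth$strain %in% tb$strain])
})

test_that("noiseless depths encode the competitive-mapping signature", {
  cfg <- tiny_config(het_fraction = 0.5)
  sim <- simulate_dataset(cfg)
  d <- sim$depths
  ann <- sim$parental$annotation
  intro <- sim$truth[sim$truth$state != "absent", ]
  i <- sample(seq_len(nrow(intro)), min(20, nrow(intro)))
  for (r in i) {
    key <- d$strain == intro$strain[r]
    pd <- d$gene_depth[key & d$gene_id == intro$gene_id[r]]
    ortho <- ann$ortholog_id[ann$gene_id == intro$gene_id[r]]
    cd <- d$gene_depth[key & d$gene_id == ortho]
    if (intro$state[r] == "introgressed_hom") {
      expect_equal(pd, cfg$mean_depth)
      expect_equal(cd, 0)
    } else {
      expect_equal(pd / cd, 1.0)  # het: depth split 50/50
    }
  }
  # absent paradoxus genes have zero coverage
  ab <- sim$truth[sim$truth$state == "absent", ][1, ]
  expect_equal(d$gene_depth[d$strain == ab$strain & d$gene_id == ab$gene_id], 0)
})

test_that("poisson depth means converge to the expectation", {
  cfg <- sim_config(n_clades = 1, strains_per_clade = 1, n_chromosomes = 1,
                    genes_per_chromosome = 1000, gene_length = 100,
                    intergenic_length = 20, block_rate = 0,
                    depth_model = "poisson", mean_depth = 150, seed = 5)
  sim <- simulate_dataset(cfg)
  cer <- sim$depths[sim$depths$subgenome == "cer", ]
  expect_equal(nrow(cer), 1000)
  expect_lt(abs(mean(cer$gene_depth) - 150) / 150, 0.02)
})

test_that("geography is clade-structured and degenerate cases behave", {
  cfg <- tiny_config()
  roster <- strain_roster(cfg)
  geo <- simulate_geography(cfg, roster)
  gd <- geographic_distance(geo)
  same <- outer(geo$clade, geo$clade, "==") & upper.tri(gd)
  diff <- outer(geo$clade, geo$clade, "!=") & upper.tri(gd)
  expect_gt(min(gd[diff]), max(gd[same]))

  # all strains at one point: all-zero distances
  one <- tibble::tibble(strain = c("a", "b"), lon = c(3, 3), lat = c(7, 7))
  expect_true(all(geographic_distance(one) == 0))
})

test_that("without isolation by distance the Mantel r is centered on zero", {
  rs <- vapply(1:50, function(s) {
    cfg <- sim_config(n_clades = 3, strains_per_clade = 4,
                      n_chromosomes = 1, genes_per_chromosome = 20,
                      gene_length = 300, intergenic_length = 100,
                      ibd_strength = 0, clade_drift_sd = 0.5,
                      block_rate = 0, background_site_rate = 0.01,
                      seed = s)
    roster <- strain_roster(cfg)
    geo <- simulate_geography(cfg, roster)
    # shuffled clade labels decouple geography from genetics entirely
    geo$lat <- sample(geo$lat); geo$lon <- sample(geo$lon)
    bg <- simulate_background_snps(cfg, NULL, roster, geo)
    ibs <- ibs_matrix(bg)
    gd <- geographic_distance(geo)
    v1 <- (1 - ibs)[lower.tri(ibs)]
    v2 <- gd[lower.tri(gd)]
    stats::cor(v1, v2, method = "spearman")
  }, numeric(1))
  expect_lt(abs(mean(rs)), 0.1)
})

test_that("ground-truth state frequencies match the config rates", {
  cfg <- sim_config(n_clades = 4, strains_per_clade = 8, n_chromosomes = 4,
                    genes_per_chromosome = 40, gene_length = 200,
                    intergenic_length = 50, het_fraction = 0.3,
                    block_rate = 6, seed = 21)
  sim <- simulate_dataset(cfg)
  intro <- sim$truth[sim$truth$state != "absent", ]
  expect_gt(nrow(intro), 1000)
  # het fraction of planted blocks within binomial 99% bounds
  tb <- sim$truth_blocks
  phat <- mean(tb$any_het)
  se <- sqrt(0.3 * 0.7 / nrow(tb))
  expect_lt(abs(phat - 0.3), 2.58 * se + 0.05)
})
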