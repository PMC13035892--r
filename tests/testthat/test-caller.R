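# minimal two-gene (one ortholog pair) annotation plus a summary row pair
pair_annotation <- function(divergence = 0.06) {
  tibble::tibble(
    gene_id = c("cer_01_001", "par_01_001"),
    subgenome = c("cer", "par"),
    chrom = c("Scer_chr01", "Spar_chr01"),
    start = 101, end = 200, order_index = 1L,
    ortholog_id = c("par_01_001", "cer_01_001"),
    ortholog_divergence = divergence, n_diff_sites = round(divergence * 100))
}

pair_summary <- function(par_depth, cer_depth, frac = 1, median = 150) {
  tibble::tibble(
    strain = "s1",
    gene_id = c("cer_01_001", "par_01_001"),
    subgenome = c("cer", "par"),
    frac_above_threshold = c(1, frac),
    gene_depth = c(cer_depth, par_depth),
    strain_median = median)
}

test_that("the three calling criteria act as documented", {
  # clean homozygous signal: called
  calls <- call_introgressed_genes(pair_summary(150, 0, frac = 0.6),
                                   pair_annotation())
  expect_identical(calls$state, "introgressed_hom")

  # covered fraction exactly one half is not "over half": absent
  calls <- call_introgressed_genes(pair_summary(150, 0, frac = 0.5),
                                   pair_annotation())
  expect_identical(calls$state, "absent")

  # divergence below 5%: absent even with perfect depth evidence
  calls <- call_introgressed_genes(pair_summary(150, 0, frac = 1),
                                   pair_annotation(divergence = 0.04))
  expect_identical(calls$state, "absent")
  # and exactly 5% passes (inclusive minimum)
  calls <- call_introgressed_genes(pair_summary(150, 0, frac = 1),
                                   pair_annotation(divergence = 0.05))
  expect_identical(calls$state, "introgressed_hom")

  # not the deepest ortholog and under 25% of its depth: absent
  calls <- call_introgressed_genes(pair_summary(30, 150), pair_annotation())
  expect_identical(calls$state, "absent")
  # exactly 25% of the ortholog depth passes (inclusive)
  calls <- call_introgressed_genes(pair_summary(37.5, 150), pair_annotation())
  expect_identical(calls$state, "introgressed_het")
})

test_that("zygosity follows the closed depth-ratio interval", {
  expect_identical(classify_zygosity(1.0), "introgressed_het")
  expect_identical(classify_zygosity(Inf), "introgressed_hom")
  expect_identical(classify_zygosity(4.0), "introgressed_het")  # inclusive
  expect_identical(classify_zygosity(4.0000001), "introgressed_hom")
  expect_error(classify_zygosity(0.2), "impossible")

  # par 150 / cer 0 flows through the caller as homozygous with Inf ratio
  calls <- call_introgressed_genes(pair_summary(150, 0), pair_annotation())
  expect_identical(calls$depth_ratio, Inf)
  # par 150 / cer 37.5 is ratio 4: het by the inclusive bound
  calls <- call_introgressed_genes(pair_summary(150, 37.5), pair_annotation())
  expect_identical(calls$state, "introgressed_het")
})

test_that("blocks are maximal same-chromosome runs", {
  ann <- tibble::tibble(
    gene_id = c(sprintf("par_01_%03d", 1:6), "par_02_001"),
    subgenome = "par",
    chrom = c(rep("Spar_chr01", 6), "Spar_chr02"),
    start = c(seq(1, 501, by = 100), 1),
    end = c(seq(100, 600, by = 100), 100),
    order_index = c(1:6, 1L),
    ortholog_id = "x", ortholog_divergence = 0.1, n_diff_sites = 10)
  calls <- tibble::tibble(
    strain = "s1",
    gene_id = c(sprintf("par_01_%03d", c(1, 2, 3, 5)), "par_02_001"),
    state = "introgressed_hom", depth_ratio = Inf)
  blocks <- assemble_blocks(calls, ann)
  expect_identical(nrow(blocks), 3L)
  expect_identical(sort(blocks$n_genes), c(1L, 1L, 3L))
  expect_identical(blocks$gene_ids[[which(blocks$n_genes == 3)]],
                   sprintf("par_01_%03d", 1:3))
  # chromosome boundary splits runs even at consecutive order indices
  calls2 <- tibble::tibble(strain = "s1",
                           gene_id = c("par_01_006", "par_02_001"),
                           state = "introgressed_hom", depth_ratio = Inf)
  expect_identical(nrow(assemble_blocks(calls2, ann)), 2L)
  # single gene forms a singleton block; empty input an empty table
  calls3 <- calls2[1, ]
  expect_identical(assemble_blocks(calls3, ann)$n_genes, 1L)
  expect_identical(nrow(assemble_blocks(calls3[0, ], ann)), 0L)
})

test_that("per-strain summaries count states and heterozygous fractions", {
  calls <- tibble::tibble(
    strain = rep(c("a", "b"), c(12, 3)),
    gene_id = sprintf("par_01_%03d", c(1:12, 1:3)),
    state = c(rep("introgressed_hom", 7), rep("introgressed_het", 3),
              rep("absent", 2), rep("absent", 3)),
    depth_ratio = 1)
  s <- summarize_strain_introgression(calls)
  expect_identical(s$n_introgressed[s$strain == "a"], 10)
  expect_equal(s$het_fraction[s$strain == "a"], 0.3)
  expect_identical(s$n_introgressed[s$strain == "b"], 0)
  expect_true(is.na(s$het_fraction[s$strain == "b"]))
})

test_that("gene summaries from per-position depths match direct counting", {
  ann <- tibble::tibble(
    gene_id = c("cer_01_001", "cer_01_002"), subgenome = "cer",
    chrom = "Scer_chr01", start = c(1, 101), end = c(100, 200),
    order_index = 1:2, ortholog_id = NA_character_,
    ortholog_divergence = NA_real_, n_diff_sites = NA_integer_)
  pos <- tibble::tibble(
    strain = "s1", chrom = "Scer_chr01", pos = 1:200,
    depth = c(rep(100, 100), rep(26, 50), rep(0, 50)))
  s <- summarize_gene_depths(pos, ann, median_scope = "concatenated")
  # median depth of this profile is 63: threshold 15.75
  expect_equal(s$frac_above_threshold[s$gene_id == "cer_01_001"], 1.0)
  expect_equal(s$frac_above_threshold[s$gene_id == "cer_01_002"], 0.5)
  expect_equal(s$gene_depth[s$gene_id == "cer_01_002"], (26 * 50) / 100)

  # uniform coverage: every gene fully covered
  pos_u <- tibble::tibble(strain = "s1", chrom = "Scer_chr01", pos = 1:200,
                          depth = 100)
  su <- summarize_gene_depths(pos_u, ann)
  expect_true(all(su$frac_above_threshold == 1.0))

  # zero-coverage strain is excluded with a warning
  pos_0 <- tibble::tibble(strain = "s2", chrom = "Scer_chr01", pos = 1:200,
                          depth = 0)
  expect_warning(expect_error(summarize_gene_depths(pos_0, ann),
                              "no analyzable strains"),
                 "median depth 0")
})

test_that("summarizer output agrees with the simulator's gene table", {
  cfg <- sim_config(n_clades = 1, strains_per_clade = 2, n_chromosomes = 1,
                    genes_per_chromosome = 6, gene_length = 80,
                    intergenic_length = 20, block_rate = 1, seed = 9)
  sim <- simulate_dataset(cfg)
  pos <- simulate_position_depths(cfg, sim$truth, sim$parental$annotation)
  s <- summarize_gene_depths(pos, sim$parental$annotation)
  key <- function(d) paste(d$strain, d$gene_id)
  d0 <- sim$depths
  m <- match(key(s), key(d0))
  expect_equal(s$gene_depth, d0$gene_depth[m])
  expect_equal(s$frac_above_threshold, d0$frac_above_threshold[m])
  expect_equal(s$strain_median, d0$strain_median[m])
})

test_that("raising the divergence threshold never adds calls", {
  cfg <- tiny_config()
  sim <- simulate_dataset(cfg)
  prev <- NULL
  for (thr in c(0.02, 0.05, 0.10, 0.15)) {
    calls <- call_introgressed_genes(sim$depths, sim$parental$annotation,
                                     min_divergence = thr)
    cur <- paste(calls$strain, calls$gene_id)[calls$state != "absent"]
    if (!is.null(prev)) expect_true(all(cur %in% prev))
    prev <- cur
  }
})

test_that("noiseless calls and blocks equal the planted truth exactly", {
  cfg <- tiny_config(het_fraction = 0.4)
  sim <- simulate_dataset(cfg)
  calls <- call_introgressed_genes(sim$depths, sim$parental$annotation)
  ev <- evaluate_calls(calls, sim$truth)
  expect_equal(ev$precision, 1)
  expect_equal(ev$recall, 1)
  expect_equal(ev$zygosity_accuracy, 1)
  blocks <- assemble_blocks(calls, sim$parental$annotation)
  expect_true(evaluate_blocks(blocks, sim$truth_blocks)$identical)
})

test_that("single-reference SNV counts exceed competitive counts iff planted", {
  cfg <- tiny_config()
  sim <- simulate_dataset(cfg)
  counts <- snv_reference_counts(sim)
  introgressed <- unique(sim$truth$strain[sim$truth$state != "absent"])
  expect_true(all(counts$n_snv_single_ref >= counts$n_snv_competitive))
  expect_true(all(counts$n_snv_single_ref[counts$strain %in% introgressed] >
                    counts$n_snv_competitive[counts$strain %in% introgressed]))

  cfg0 <- tiny_config(block_rate = 0)
  counts0 <- snv_reference_counts(simulate_dataset(cfg0))
  expect_identical(counts0$n_snv_single_ref, counts0$n_snv_competitive)
})
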