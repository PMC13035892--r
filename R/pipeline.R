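#' Pipeline configuration with the study's default thresholds
#'
#' Collects every tunable of the calling, validation, assignment and
#' statistics stages, with defaults equal to the published analysis:
#' covered fraction > 0.5 at 25% of the median depth, ortholog depth
#' factor 0.25, minimum ortholog divergence 0.05, heterozygous depth-ratio
#' interval [0.25, 4], site filters DP >= 5 / QUAL >= 30 / 90% call rate,
#' structure filters 1% site and 10% strain missingness, LD pruning
#' 50/5/0.5, 10-kb windows, 9999 Mantel permutations.
#'
#' @param sim A [sim_config()] describing the synthetic inputs.
#' @param out_dir Optional output directory for stage files.
#' @param seed Analysis seed (permutations); independent of the
#'   simulation seed.
#' @param ... Threshold overrides (see defaults in the function body).
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(sim = sim_config(), out_dir = NULL, seed = 1,
                            ...) {
  cfg <- list(
    sim = sim, out_dir = out_dir, seed = seed,
    min_depth = 5, min_qual = 30, min_call_rate = 0.90,
    max_site_missing = 0.01, max_strain_missing = 0.10,
    ld_window = 50, ld_step = 5, ld_r2_max = 0.5,
    min_covered_frac = 0.5, ortholog_depth_factor = 0.25,
    min_divergence = 0.05, het_ratio_low = 0.25, het_ratio_high = 4.0,
    origin_tie_tol = 1e-6, validation_tol = 1e-9,
    window = 10000, n_perm = 9999, min_carriers = 1)
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  abort_if(length(unknown) > 0, "pipeline_config: unknown option(s): ",
           paste(unknown, collapse = ", "))
  cfg[names(dots)] <- dots
  class(cfg) <- "pipeline_config"
  cfg
}

#' Run the full analysis end-to-end on a synthetic dataset
#'
#' Stages, in order: simulate, site filters, introgression calling, block
#' assembly, phylogenetic validation, donor-origin assignment, retention
#' analysis, population-genetic statistics, and a recovery report against
#' the recorded ground truth. With `out_dir` set, all stage outputs and a
#' manifest with per-file checksums are written; re-running an unchanged
#' config reproduces identical files.
#'
#' @param config A [pipeline_config()].
#' @return A result bundle (list) with all stage outputs.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  sim <- stage("simulate", simulate_dataset(config$sim))
  ann <- sim$parental$annotation

  # population-structure substrate: resident-subgenome SNPs, site filters
  cer_gm <- stage("filter", {
    g <- gm_subgenome(sim$focal_gm, "Scer_")
    filter_sites(g, config$min_depth, config$min_qual,
                 config$min_call_rate)
  })
  struct_gm <- stage("filter", filter_for_structure(
    cer_gm, config$max_site_missing, config$max_strain_missing))
  pruned_idx <- stage("filter", ld_prune(struct_gm, config$ld_window,
                                         config$ld_step, config$ld_r2_max))
  struct_gm <- gm_subset(struct_gm, sites = pruned_idx)

  calls <- stage("call", call_introgressed_genes(
    sim$depths, ann, config$min_covered_frac,
    config$ortholog_depth_factor, config$min_divergence,
    config$het_ratio_low, config$het_ratio_high))
  blocks <- stage("call", assemble_blocks(calls, ann))

  panel <- stage("validate", build_validation_panel(sim$parental, sim$donor))
  blocks <- stage("validate", validate_blocks(blocks, sim$focal_gm, ann,
                                              panel, config$validation_tol))

  par_gm <- gm_subgenome(sim$focal_gm, "Spar_")
  blocks <- stage("assign", assign_block_origins(
    blocks[blocks$validated != "rejected", , drop = FALSE],
    par_gm, ann, sim$donor$gm, sim$donor$lineages, config$origin_tie_tol))
  gene_origins <- propagate_block_origin(blocks)
  origin_counts <- summarize_origin_counts(gene_origins, sim$roster)

  retention <- stage("retention", build_presence_matrices(
    calls, sim$roster, config$min_carriers))
  universe <- sum(ann$subgenome == "par" &
                    ann$ortholog_divergence >= config$min_divergence)
  shared <- if (length(retention$clade_sets) >= 2)
    multiway_shared_genes(retention$clade_sets) else NULL
  retention_cluster <- if (nrow(retention$clade_fractions) >= 2 &&
                             ncol(retention$clade_fractions) >= 1)
    cluster_retention_patterns(retention$clade_fractions) else NULL

  popgen <- stage("popgen", {
    ibs <- ibs_matrix(struct_gm)
    geo <- geographic_distance(sim$geography)
    mantel <- mantel_spearman(1 - ibs, geo[struct_gm$strains,
                                           struct_gm$strains],
                              n_perm = config$n_perm, seed = config$seed)
    list(
      pi = windowed_pi(struct_gm, config$window),
      tajima_d = windowed_tajimas_d(struct_gm, config$window),
      heterozygosity = strain_heterozygosity(cer_gm),
      ibs = ibs,
      mds = mds_embedding(1 - ibs),
      mantel = mantel)
  })

  report <- list(
    strain_summary = summarize_strain_introgression(calls, blocks),
    recovery = list(calls = evaluate_calls(calls, sim$truth),
                    blocks = evaluate_blocks(blocks, sim$truth_blocks),
                    origins = evaluate_origins(blocks, sim$truth_blocks)),
    mantel = popgen$mantel)

  bundle <- list(config = config, sim = sim, filtered_gm = cer_gm,
                 structure_gm = struct_gm, calls = calls, blocks = blocks,
                 gene_origins = gene_origins,
                 origin_counts = origin_counts, retention = retention,
                 shared_genes = shared, universe_size = universe,
                 retention_cluster = retention_cluster, popgen = popgen,
                 report = report)
  if (!is.null(config$out_dir)) write_pipeline_outputs(bundle)
  invisible(bundle)
}

write_pipeline_outputs <- function(bundle) {
  out <- bundle$config$out_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  write_dataset(bundle$sim, file.path(out, "inputs"))
  p <- function(f) file.path(out, f)
  write_tsv_file(bundle$calls, p("introgression_calls.tsv"))
  bl <- bundle$blocks
  write_tsv_file(bl, p("introgression_blocks.tsv"))
  if (nrow(bl) > 0)
    write_bed(bl[, c("chrom", "start", "end")], p("introgression_blocks.bed"))
  write_tsv_file(bundle$gene_origins, p("gene_origins.tsv"))
  write_tsv_file(bundle$origin_counts$per_clade, p("origin_counts_by_clade.tsv"))
  write_matrix_tsv(bundle$retention$clade_fractions, p("clade_gene_fractions.tsv"))
  if (!is.null(bundle$retention_cluster))
    writeLines(bundle$retention_cluster$newick, p("retention_dendrogram.nwk"))
  write_tsv_file(bundle$popgen$pi, p("windowed_pi.tsv"))
  write_tsv_file(bundle$popgen$tajima_d, p("windowed_tajima_d.tsv"))
  write_tsv_file(tibble::tibble(strain = names(bundle$popgen$heterozygosity),
                                het_ratio = bundle$popgen$heterozygosity),
                 p("strain_heterozygosity.tsv"))
  write_matrix_tsv(bundle$popgen$ibs, p("ibs_matrix.tsv"))
  write_matrix_tsv(bundle$popgen$mds, p("mds_coordinates.tsv"))
  write_tsv_file(bundle$report$strain_summary, p("strain_summary.tsv"))
  rel <- setdiff(list.files(out, recursive = TRUE), "manifest.json")
  rel <- rel[basename(rel) != "manifest.json"]
  manifest <- list(
    package = "introgressr",
    version = as.character(utils::packageVersion("introgressr")),
    seed = bundle$config$seed,
    config = unclass(bundle$config)[setdiff(names(bundle$config),
                                            c("sim", "out_dir"))],
    sim_config = unclass(bundle$config$sim),
    checksums = as.list(stats::setNames(
      unname(tools::md5sum(file.path(out, rel))), rel)))
  jsonlite::write_json(manifest, p("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  invisible(out)
}
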