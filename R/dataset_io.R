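#' Write parental genomes as FASTA
#'
#' @param genomes Named list of per-chromosome base vectors.
#' @param path Output FASTA path.
#' @return `path`, invisibly.
#' @export
write_genome_fasta <- function(genomes, path) {
  seqs <- Biostrings::DNAStringSet(vapply(genomes, paste, character(1),
                                          collapse = ""))
  names(seqs) <- names(genomes)
  Biostrings::writeXStringSet(seqs, path)
  invisible(path)
}

#' Read a FASTA genome back into per-chromosome base vectors
#' @param path FASTA path.
#' @return Named list of character vectors.
#' @export
read_genome_fasta <- function(path) {
  seqs <- Biostrings::readDNAStringSet(path)
  out <- lapply(as.character(seqs), function(s) strsplit(s, "")[[1]])
  names(out) <- names(seqs)
  out
}

#' Write the gene annotation as GFF3 plus an ortholog-map TSV
#'
#' The GFF3 carries gene coordinates (1-based inclusive) with `ID`
#' attributes; ortholog pairing and per-ortholog divergence live in a
#' sidecar TSV since GFF3 has no standard slot for them.
#'
#' @param annotation Annotation tibble.
#' @param gff_path GFF3 output path.
#' @param ortholog_path Ortholog-map TSV output path.
#' @return Invisibly, the two paths.
#' @export
write_annotation <- function(annotation, gff_path, ortholog_path) {
  gr <- GenomicRanges::GRanges(
    seqnames = annotation$chrom,
    ranges = IRanges::IRanges(annotation$start, annotation$end),
    strand = "+",
    type = "gene",
    ID = annotation$gene_id)
  rtracklayer::export(gr, gff_path, format = "gff3")
  write_tsv_file(annotation[, c("gene_id", "subgenome", "order_index",
                                "ortholog_id", "ortholog_divergence",
                                "n_diff_sites")],
                 ortholog_path)
  invisible(c(gff_path, ortholog_path))
}

#' Read a gene annotation from GFF3 plus ortholog-map TSV
#'
#' @param gff_path GFF3 path (type `gene`, `ID` attributes).
#' @param ortholog_path Ortholog-map TSV written by [write_annotation()].
#' @return Annotation tibble.
#' @export
read_annotation <- function(gff_path, ortholog_path) {
  gr <- rtracklayer::import(gff_path, format = "gff3")
  gr <- gr[gr$type == "gene"]
  tbl <- tibble::tibble(
    gene_id = gr$ID,
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr),
    end = GenomicRanges::end(gr))
  ortho <- read_tsv_file(ortholog_path)
  out <- merge(tbl, ortho, by = "gene_id", sort = FALSE)
  out <- tibble::as_tibble(out)
  out <- out[order(out$chrom, out$start), ]
  out[, c("gene_id", "subgenome", "chrom", "start", "end", "order_index",
          "ortholog_id", "ortholog_divergence", "n_diff_sites")]
}

#' Write a complete synthetic dataset to disk
#'
#' Emits the standard file bundle: subgenome FASTA references, GFF3 + TSV
#' annotation, focal and donor-panel VCFs, depth-summary TSV, strain
#' metadata (clades, coordinates, donor lineages), ground-truth TSVs, and
#' a manifest JSON recording the config and per-file MD5 checksums.
#'
#' @param sim Output of [simulate_dataset()].
#' @param out_dir Output directory (created if missing).
#' @return Named vector of file paths, invisibly.
#' @export
write_dataset <- function(sim, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(out_dir, f)
  paths <- c(
    reference = p("reference_concat.fasta"),
    gff = p("genes.gff3"),
    orthologs = p("orthologs.tsv"),
    focal_vcf = p("focal.vcf"),
    donor_vcf = p("donor_panel.vcf"),
    donor_lineages = p("donor_lineages.tsv"),
    clades = p("strain_clades.tsv"),
    coords = p("strain_coordinates.tsv"),
    depths = p("gene_depths.tsv"),
    truth = p("truth_gene_states.tsv"),
    truth_blocks = p("truth_blocks.tsv"))
  write_genome_fasta(sim$parental$genomes, paths["reference"])
  write_annotation(sim$parental$annotation, paths["gff"], paths["orthologs"])
  write_vcf(sim$focal_gm, paths["focal_vcf"])
  write_vcf(sim$donor$gm, paths["donor_vcf"])
  write_tsv_file(sim$donor$lineages, paths["donor_lineages"])
  write_tsv_file(sim$roster, paths["clades"])
  write_tsv_file(sim$geography, paths["coords"])
  write_tsv_file(sim$depths, paths["depths"])
  write_tsv_file(sim$truth, paths["truth"])
  write_tsv_file(sim$truth_blocks, paths["truth_blocks"])
  manifest <- list(
    package = "introgressr",
    version = as.character(utils::packageVersion("introgressr")),
    config = unclass(sim$config),
    files = as.list(stats::setNames(unname(tools::md5sum(unname(paths))),
                                    basename(paths))))
  jsonlite::write_json(manifest, p("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  invisible(c(paths, manifest = p("manifest.json")))
}

#' Write per-position depths as a BED-like table
#'
#' One row per position: `chrom`, 0-based start, end, depth, strain.
#'
#' @param pos_depths Tibble from [simulate_position_depths()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_depth_bed <- function(pos_depths, path) {
  utils::write.table(
    data.frame(pos_depths$chrom, pos_depths$pos - 1L, pos_depths$pos,
               pos_depths$depth, pos_depths$strain),
    path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a per-position depth BED written by [write_depth_bed()]
#' @param path BED path.
#' @return Tibble with `strain`, `chrom`, `pos`, `depth`.
#' @export
read_depth_bed <- function(path) {
  df <- utils::read.table(path, sep = "\t", stringsAsFactors = FALSE)
  tibble::tibble(strain = df[[5]], chrom = df[[1]], pos = df[[3]],
                 depth = df[[4]])
}
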