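#' Read a VCF into a genotype matrix
#'
#' Parses a VCF v4.2 file (via vcfR) into a [genotype_matrix()]. Genotypes
#' are coded as allele dosage (0/1/2) with half-called or missing calls as
#' `NA`. Multiallelic records are passed through with `NA` dosage and are
#' flagged so the biallelic-SNP filter removes them; they are never silently
#' dropped at parse time.
#'
#' @param path Path to a VCF file (plain text or bgzipped).
#' @return A `genotype_matrix`; per-strain depth is populated when the VCF
#'   carries a `DP` FORMAT field.
#' @export
read_vcf <- function(path) {
  abort_if(!file.exists(path), "read_vcf: no such file: ", path)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  if (nrow(fix) == 0) {
    strains <- colnames(v@gt)
    strains <- strains[strains != "FORMAT"]
    if (length(strains) == 0) strains <- character(0)
    gt <- matrix(integer(0), nrow = 0, ncol = length(strains),
                 dimnames = list(NULL, strains))
    return(genotype_matrix(
      tibble::tibble(chrom = character(0), pos = integer(0),
                     ref = character(0), alt = character(0),
                     qual = numeric(0)),
      gt, matrix(numeric(0), 0, length(strains), dimnames = list(NULL, strains))))
  }
  sites <- tibble::tibble(
    chrom = fix$CHROM,
    pos = as.integer(fix$POS),
    ref = fix$REF,
    alt = ifelse(is.na(fix$ALT), ".", fix$ALT),
    qual = suppressWarnings(as.numeric(fix$QUAL))
  )
  gt_raw <- vcfR::extract.gt(v, element = "GT")
  gt <- gt_dosage(gt_raw)
  # dosage is undefined for multiallelic records; the SNP filter drops them
  multi <- grepl(",", sites$alt, fixed = TRUE)
  gt[multi, ] <- NA_integer_
  dp <- NULL
  fmt <- v@gt[, "FORMAT"]
  if (any(grepl("(^|:)DP(:|$)", fmt))) {
    dp <- suppressWarnings(vcfR::extract.gt(v, element = "DP", as.numeric = TRUE))
    dimnames(dp) <- dimnames(gt)
  }
  genotype_matrix(sites, gt, dp)
}

gt_dosage <- function(gt_raw) {
  code <- c("0/0" = 0L, "0|0" = 0L,
            "0/1" = 1L, "1/0" = 1L, "0|1" = 1L, "1|0" = 1L,
            "1/1" = 2L, "1|1" = 2L)
  out <- matrix(unname(code[gt_raw]), nrow = nrow(gt_raw),
                dimnames = dimnames(gt_raw))
  storage.mode(out) <- "integer"
  out
}

#' Write a genotype matrix as a plain-text VCF v4.2
#'
#' Emits `GT:DP` per strain; missing genotypes are written as `./.`.
#' A write-then-read round trip preserves genotypes, QUAL and depth.
#'
#' @param gm A [genotype_matrix()].
#' @param path Output path.
#' @param source Free-text `##source` header value.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(gm, path, source = "introgressr") {
  gt_str <- matrix("./.", nrow = nrow(gm$gt), ncol = ncol(gm$gt))
  gt_str[which(gm$gt == 0L)] <- "0/0"
  gt_str[which(gm$gt == 1L)] <- "0/1"
  gt_str[which(gm$gt == 2L)] <- "1/1"
  if (!is.null(gm$dp)) {
    dp_str <- ifelse(is.na(gm$dp), ".", format(gm$dp, trim = TRUE, scientific = FALSE))
    cells <- matrix(paste0(gt_str, ":", dp_str), nrow = nrow(gt_str))
  } else {
    cells <- gt_str
  }
  fmt <- if (!is.null(gm$dp)) "GT:DP" else "GT"
  qual <- ifelse(is.na(gm$sites$qual), ".",
                 format(gm$sites$qual, trim = TRUE, scientific = FALSE))
  header <- c(
    "##fileformat=VCFv4.2",
    paste0("##source=", source),
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    if (!is.null(gm$dp))
      "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", gm$strains), collapse = "\t")
  )
  body <- if (nrow(gm$sites) > 0) {
    paste(gm$sites$chrom, gm$sites$pos, ".", gm$sites$ref, gm$sites$alt,
          qual, "PASS", ".", fmt,
          apply(cells, 1, paste, collapse = "\t"),
          sep = "\t")
  } else character(0)
  writeLines(c(header, body), path)
  invisible(path)
}

#' Write site spans as a BED file (0-based, half-open)
#'
#' @param tbl Data frame with `chrom`, `start`, `end` (1-based inclusive
#'   coordinates) and optionally `name`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(tbl, path) {
  name <- if ("name" %in% names(tbl)) tbl$name else "."
  utils::write.table(
    data.frame(tbl$chrom, tbl$start - 1L, tbl$end, name),
    path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}
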