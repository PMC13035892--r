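#' Compare gene-state calls against simulated ground truth
#'
#' @param calls Call table from [call_introgressed_genes()].
#' @param truth Truth table from [simulate_dataset()].
#' @return A list with gene-level `precision`, `recall` and `accuracy`
#'   for presence (state != absent), `state_accuracy` over all
#'   strain-gene pairs (exact three-way state match), `zygosity_accuracy`
#'   over truly introgressed genes, and the underlying counts.
#' @export
evaluate_calls <- function(calls, truth) {
  key <- function(s, g) paste(s, g)
  t_state <- stats::setNames(truth$state, key(truth$strain, truth$gene_id))
  c_state <- t_state
  c_state[] <- "absent"
  ck <- key(calls$strain, calls$gene_id)
  c_state[ck] <- calls$state
  called_pos <- c_state != "absent"
  true_pos <- t_state != "absent"
  tp <- sum(called_pos & true_pos)
  fp <- sum(called_pos & !true_pos)
  fn <- sum(!called_pos & true_pos)
  zyg <- c_state[true_pos] == t_state[true_pos]
  list(precision = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
       recall = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
       accuracy = mean(called_pos == true_pos),
       state_accuracy = mean(c_state == t_state),
       zygosity_accuracy = if (length(zyg)) mean(zyg) else NA_real_,
       n_true = sum(true_pos), n_called = sum(called_pos),
       tp = tp, fp = fp, fn = fn)
}

#' Compare assembled blocks against ground-truth blocks
#'
#' Blocks are identified by strain plus their exact gene set.
#'
#' @param blocks Block table from [assemble_blocks()].
#' @param truth_blocks Truth blocks from [simulate_dataset()].
#' @return A list with `identical` (set equality), `jaccard`, and counts.
#' @export
evaluate_blocks <- function(blocks, truth_blocks) {
  sig <- function(b) paste(b$strain,
                           vapply(b$gene_ids, paste, character(1),
                                  collapse = ","))
  a <- sig(blocks); b <- sig(truth_blocks)
  inter <- length(intersect(a, b))
  uni <- length(union(a, b))
  list(identical = setequal(a, b),
       jaccard = if (uni > 0) inter / uni else 1,
       n_called = length(a), n_true = length(b), n_matching = inter)
}

#' Donor-assignment accuracy against ground truth
#'
#' Matches assigned blocks to truth blocks by strain and gene overlap and
#' scores the fraction of assigned blocks whose origin equals the planted
#' donor lineage.
#'
#' @param blocks Block table with origin columns.
#' @param truth_blocks Truth blocks.
#' @param min_genes Only consider blocks with at least this many genes.
#' @return A list with `accuracy` (over assigned blocks), `n_assigned`,
#'   `n_unassigned`, `n_scored`.
#' @export
evaluate_origins <- function(blocks, truth_blocks, min_genes = 1) {
  truth_lineage <- list()
  for (i in seq_len(nrow(truth_blocks))) {
    for (g in truth_blocks$gene_ids[[i]])
      truth_lineage[[paste(truth_blocks$strain[i], g)]] <-
        truth_blocks$donor_lineage[i]
  }
  scored <- 0L; correct <- 0L; unassigned <- 0L
  for (i in seq_len(nrow(blocks))) {
    if (blocks$n_genes[i] < min_genes) next
    truths <- unlist(truth_lineage[paste(blocks$strain[i],
                                         blocks$gene_ids[[i]])])
    if (is.null(truths)) next
    expected <- names(sort(table(truths), decreasing = TRUE))[1]
    if (!isTRUE(blocks$assigned[i])) {
      unassigned <- unassigned + 1L
      next
    }
    scored <- scored + 1L
    if (blocks$origin[i] == expected) correct <- correct + 1L
  }
  list(accuracy = if (scored > 0) correct / scored else NA_real_,
       n_assigned = scored, n_unassigned = unassigned,
       n_scored = scored + unassigned)
}
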