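#' Fold-change contrast for a flagged gene set (3'UTR shortening)
#'
#' For each mapped protein-gene pair, the paired tumor-minus-normal
#' median log2 fold change over complete tissue pairs is computed on the
#' transformed protein scale and on the mRNA scale.  The flagged set is
#' contrasted against all remaining genes with a two-sided Wilcoxon
#' rank-sum test on the per-gene folds (a Welch t-test is reported
#' alongside), separately for protein and mRNA.  Group fold changes are
#' summarized as `2^mean(log2 fold)` (geometric mean), or `2^median`
#' with `summary = "median"`.
#'
#' @param protein an `omics_matrix` of transformed protein values.
#' @param mrna an `omics_matrix` of mRNA log2 intensities.
#' @param pairs a [pair_map()] linking protein to gene ids.
#' @param clinical a `sample_table` with `tissue` and `pair_id` (>= 6
#'   complete pairs required).
#' @param gene_set character vector of flagged gene ids (>= 10 must map).
#' @param summary `"mean"` (default) or `"median"` log2-fold summary.
#' @return a `foldchange_contrast` list: `n_mapped`, `n_background`,
#'   `set_protein_fc`, `background_protein_fc`, `set_mrna_fc`,
#'   `background_mrna_fc`, `protein_p` / `mrna_p` (rank-sum),
#'   `protein_p_t` / `mrna_p_t` (Welch), and `per_gene` (a data.frame of
#'   per-gene folds with the set flag).
#' @export
foldchange_contrast <- function(protein, mrna, pairs, clinical, gene_set,
                                summary = c("mean", "median")) {
  summary <- match.arg(summary)
  cl <- clinical[!is.na(clinical$pair_id) & clinical$pair_id != "", ]
  tum <- cl[cl$tissue == "tumor", ]
  nor <- cl[cl$tissue == "normal", ]
  common <- intersect(tum$pair_id, nor$pair_id)
  tum_id <- tum$sample_id[match(common, tum$pair_id)]
  nor_id <- nor$sample_id[match(common, nor$pair_id)]
  keep <- tum_id %in% protein$sample_ids & nor_id %in% protein$sample_ids &
    tum_id %in% mrna$sample_ids & nor_id %in% mrna$sample_ids
  tum_id <- tum_id[keep]; nor_id <- nor_id[keep]
  if (length(tum_id) < 6L) stop("need at least 6 complete tissue pairs")
  use <- pairs$protein_id %in% protein$feature_ids &
    pairs$gene_id %in% mrna$feature_ids
  pm <- pairs[use, , drop = FALSE]
  in_set <- pm$gene_id %in% gene_set
  if (sum(in_set) < 10L) stop("fewer than 10 flagged genes map to the data")
  med_fold <- function(mat, ids) {
    d <- mat[ids, tum_id, drop = FALSE] - mat[ids, nor_id, drop = FALSE]
    apply(d, 1L, stats::median, na.rm = TRUE)
  }
  prot_fold <- med_fold(protein$values, pm$protein_id)
  mrna_fold <- med_fold(mrna$values, pm$gene_id)
  summarize <- function(x) if (summary == "mean") mean(x, na.rm = TRUE)
    else stats::median(x, na.rm = TRUE)
  contrast <- function(folds) {
    x <- folds[in_set]; y <- folds[!in_set]
    list(set_fc = 2^summarize(x), bg_fc = 2^summarize(y),
         p_ranksum = ranksum_test(x, y)$p,
         p_t = stats::t.test(x, y)$p.value)
  }
  pc <- contrast(prot_fold)
  mc <- contrast(mrna_fold)
  structure(list(
    n_mapped = sum(in_set), n_background = sum(!in_set),
    n_pairs = length(tum_id), summary = summary,
    set_protein_fc = pc$set_fc, background_protein_fc = pc$bg_fc,
    set_mrna_fc = mc$set_fc, background_mrna_fc = mc$bg_fc,
    protein_p = pc$p_ranksum, protein_p_t = pc$p_t,
    mrna_p = mc$p_ranksum, mrna_p_t = mc$p_t,
    per_gene = data.frame(protein_id = pm$protein_id, gene_id = pm$gene_id,
                          protein_log2fc = prot_fold,
                          mrna_log2fc = mrna_fold, in_set = in_set,
                          stringsAsFactors = FALSE)),
    class = "foldchange_contrast")
}

#' @export
print.foldchange_contrast <- function(x, ...) {
  cat(sprintf(paste0("<foldchange_contrast> %d set / %d background genes,",
                     " %d pairs\n  protein: set %.2f-fold vs background",
                     " %.2f-fold (rank-sum p = %.3g)\n  mRNA:    set %.2f",
                     "-fold vs background %.2f-fold (rank-sum p = %.3g)\n"),
              x$n_mapped, x$n_background, x$n_pairs,
              x$set_protein_fc, x$background_protein_fc, x$protein_p,
              x$set_mrna_fc, x$background_mrna_fc, x$mrna_p))
  invisible(x)
}
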