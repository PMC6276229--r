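#' Build the protein-mRNA pair set for a tissue group
#'
#' Pairs are kept when the protein passes the group's coverage filter
#' (detected, i.e. count > 0, in at least
#' `ceiling(min_coverage_fraction * n_group_samples)` of the group's
#' samples) and the mapped gene is present in the mRNA matrix.  Coverage
#' is computed within the given group, which is why tumor and normal pair
#' sets generally differ in size.  Pairs are ordered by protein id.
#'
#' @param protein_counts an `omics_matrix` of kind `"counts"` (detection
#'   is defined on raw counts).
#' @param mrna an `omics_matrix` with gene features.
#' @param pairs a [pair_map()].
#' @param group_samples character vector of sample ids forming the group.
#' @param min_coverage_fraction detection fraction cutoff (default 0.10).
#' @return a `pair_set`: data.frame with `protein_id`, `gene_id`, plus
#'   attributes `group_samples` and `min_coverage_fraction`.
#' @export
build_pair_set <- function(protein_counts, mrna, pairs, group_samples,
                           min_coverage_fraction = 0.10) {
  stopifnot(inherits(protein_counts, "omics_matrix"),
            protein_counts$value_kind == "counts",
            inherits(mrna, "omics_matrix"))
  group_samples <- as.character(group_samples)
  missing_s <- setdiff(group_samples, protein_counts$sample_ids)
  if (length(missing_s))
    stop("samples not in the protein matrix: ",
         paste(utils::head(missing_s, 3), collapse = ", "))
  need <- ceiling(min_coverage_fraction * length(group_samples))
  det <- rowSums(protein_counts$values[, group_samples, drop = FALSE] > 0)
  ok_prot <- protein_counts$feature_ids[det >= need]
  keep <- pairs$protein_id %in% ok_prot & pairs$gene_id %in% mrna$feature_ids
  ps <- pairs[keep, , drop = FALSE]
  ps <- ps[order(ps$protein_id), , drop = FALSE]
  rownames(ps) <- NULL
  if (!nrow(ps)) stop("empty pair set")
  structure(ps, group_samples = group_samples,
            min_coverage_fraction = min_coverage_fraction,
            class = c("pair_set", "data.frame"))
}

# Restrict a pair set to pairs resolvable in both matrices (a pair built
# on raw counts can reference a protein dropped by a later filter).
.resolve_pairs <- function(pair_set, protein, mrna) {
  keep <- pair_set$protein_id %in% protein$feature_ids &
    pair_set$gene_id %in% mrna$feature_ids
  if (!all(keep)) {
    cls <- class(pair_set)
    pair_set <- pair_set[keep, , drop = FALSE]
    class(pair_set) <- cls
  }
  if (!nrow(pair_set)) stop("no pair resolvable in both matrices")
  pair_set
}

#' Within-sample protein-mRNA concordance
#'
#' For each sample, the tie-corrected Spearman correlation, over the pair
#' set, between the sample's protein vector (transformed scale) and its
#' mRNA vector.  Pairs with a missing mRNA value are dropped for that
#' sample (pairwise-complete).  Samples with fewer than `min_pairs`
#' usable pairs score NA.
#'
#' @param protein an `omics_matrix` of transformed protein values.
#' @param mrna an `omics_matrix` of mRNA log intensities.
#' @param pair_set a `pair_set` from [build_pair_set()].
#' @param samples sample ids to score (must be in both matrices).
#' @param min_pairs minimum usable pairs per score (default 30).
#' @return a `concordance_result` data.frame with `sample_id`, `rho`,
#'   `n_used`, `reason`; attribute `mode = "within_sample"`.
#' @export
within_sample_concordance <- function(protein, mrna, pair_set, samples,
                                      min_pairs = 30L) {
  samples <- as.character(samples)
  pair_set <- .resolve_pairs(pair_set, protein, mrna)
  pv <- protein$values[pair_set$protein_id, samples, drop = FALSE]
  mv <- mrna$values[pair_set$gene_id, samples, drop = FALSE]
  res <- lapply(seq_along(samples), function(j) {
    ok <- !is.na(pv[, j]) & !is.na(mv[, j])
    if (sum(ok) < min_pairs)
      return(data.frame(rho = NA_real_, n_used = sum(ok),
                        reason = "insufficient_pairs"))
    r <- spearman_rho(pv[ok, j], mv[ok, j])
    data.frame(rho = as.numeric(r), n_used = sum(ok),
               reason = if (is.na(r)) attr(r, "reason") else "")
  })
  out <- cbind(data.frame(sample_id = samples, stringsAsFactors = FALSE),
               do.call(rbind, res))
  structure(out, mode = "within_sample", n_pairs = nrow(pair_set),
            class = c("concordance_result", "data.frame"))
}

#' Across-subject (per-pair) protein-mRNA concordance
#'
#' For each protein-mRNA pair, the tie-corrected Spearman correlation
#' between its protein and mRNA values across the given samples.
#'
#' @inheritParams within_sample_concordance
#' @param min_samples minimum samples required (default 10).
#' @return a `concordance_result` data.frame with `protein_id`, `gene_id`,
#'   `rho`, `n_used`, `reason`; attribute `mode = "across_subject"`.
#' @export
per_pair_concordance <- function(protein, mrna, pair_set, samples,
                                 min_samples = 10L) {
  samples <- as.character(samples)
  if (length(samples) < min_samples)
    stop("need at least ", min_samples, " samples")
  pair_set <- .resolve_pairs(pair_set, protein, mrna)
  pv <- protein$values[pair_set$protein_id, samples, drop = FALSE]
  mv <- mrna$values[pair_set$gene_id, samples, drop = FALSE]
  res <- lapply(seq_len(nrow(pair_set)), function(i) {
    r <- spearman_rho(pv[i, ], mv[i, ])
    data.frame(rho = as.numeric(r),
               n_used = sum(!is.na(pv[i, ]) & !is.na(mv[i, ])),
               reason = if (is.na(r)) attr(r, "reason") else "")
  })
  out <- cbind(pair_set[, c("protein_id", "gene_id")], do.call(rbind, res))
  rownames(out) <- NULL
  structure(out, mode = "across_subject", n_samples = length(samples),
            class = c("concordance_result", "data.frame"))
}

#' Compare concordance scores between groups
#'
#' Two groups: two-sided Wilcoxon rank-sum (exact for both n <= 12, else
#' tie-corrected normal approximation).  More than two groups:
#' Kruskal-Wallis with tie correction.
#'
#' @param scores numeric vector of concordance scores (NA dropped).
#' @param labels group label per score.
#' @return a `group_comparison` list: `test`, `statistic`, `p`,
#'   `group_n`, `group_mean`, `group_median`.
#' @export
compare_concordance <- function(scores, labels) {
  labels <- as.character(labels)
  if (length(scores) != length(labels))
    stop("scores and labels must have equal length")
  for (g in unique(labels))
    if (all(is.na(scores[labels == g])))
      stop("group '", g, "' has only NA scores")
  ok <- !is.na(scores)
  scores <- scores[ok]; labels <- labels[ok]
  groups <- sort(unique(labels))
  if (length(groups) < 2L) stop("need at least 2 non-empty groups")
  gm <- tapply(scores, labels, mean)
  gmed <- tapply(scores, labels, stats::median)
  gn <- tapply(scores, labels, length)
  if (length(groups) == 2L) {
    t_ <- ranksum_test(scores[labels == groups[1L]],
                       scores[labels == groups[2L]])
    out <- list(test = "wilcoxon_rank_sum", statistic = t_$statistic,
                p = t_$p, method = t_$method)
  } else {
    t_ <- kruskal_wallis(scores, labels)
    out <- list(test = "kruskal_wallis", statistic = t_$statistic,
                p = t_$p, df = t_$df)
  }
  out$group_n <- as.list(gn)
  out$group_mean <- as.list(gm)
  out$group_median <- as.list(gmed)
  class(out) <- "group_comparison"
  out
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("<group_comparison> %s: statistic = %.4g, p = %.3g\n",
              x$test, x$statistic, x$p))
  invisible(x)
}

#' Stratified within-sample concordance
#'
#' Recomputes within-sample concordance per stratum of the pair set, or
#' on the pair set minus an exclusion list.  Strata may be given as
#' per-pair labels, or chosen as `"abundance"` (sextiles of mean
#' transformed protein abundance by default) or `"coverage"` (bins of
#' the detection fraction).  Strata with fewer than `min_pairs` pairs
#' yield NA scores.
#'
#' @inheritParams within_sample_concordance
#' @param strata one of: a per-pair character/factor vector of labels
#'   (length `nrow(pair_set)`); the string `"abundance"`; the string
#'   `"coverage"` (requires `counts`); or `NULL` with `exclude` set.
#' @param exclude character vector of gene ids to drop (used when
#'   `strata` is NULL; an empty vector reproduces the unstratified
#'   result).
#' @param counts raw count `omics_matrix` (needed for `"coverage"`).
#' @param n_bins number of quantile bins for abundance/coverage strata
#'   (default 6, i.e. sextiles).
#' @return named list of `concordance_result` objects, one per stratum
#'   (or a single `"all"` entry in exclusion mode).
#' @export
stratified_concordance <- function(protein, mrna, pair_set, samples,
                                   strata = NULL, exclude = NULL,
                                   counts = NULL, n_bins = 6L,
                                   min_pairs = 30L) {
  if (is.null(strata)) {
    keep <- !(pair_set$gene_id %in% (exclude %||% character(0)))
    ps <- pair_set[keep, , drop = FALSE]
    class(ps) <- class(pair_set)
    if (!nrow(ps)) stop("exclusion removes every pair")
    return(list(all = within_sample_concordance(protein, mrna, ps, samples,
                                                min_pairs = min_pairs)))
  }
  if (is.character(strata) && length(strata) == 1L &&
      strata %in% c("abundance", "coverage")) {
    if (strata == "abundance") {
      v <- rowMeans(protein$values[pair_set$protein_id, samples,
                                   drop = FALSE], na.rm = TRUE)
    } else {
      if (is.null(counts)) stop("coverage strata require `counts`")
      v <- rowMeans(counts$values[pair_set$protein_id, samples,
                                  drop = FALSE] > 0)
    }
    br <- unique(stats::quantile(v, probs = seq(0, 1, length.out = n_bins + 1)))
    lab <- cut(v, breaks = br, include.lowest = TRUE,
               labels = paste0("bin", seq_len(length(br) - 1L)))
  } else {
    if (length(strata) != nrow(pair_set))
      stop("per-pair strata must have one label per pair")
    lab <- factor(as.character(strata))
  }
  out <- lapply(levels(lab), function(lv) {
    ps <- pair_set[lab == lv, , drop = FALSE]
    class(ps) <- class(pair_set)
    within_sample_concordance(protein, mrna, ps, samples,
                              min_pairs = min_pairs)
  })
  stats::setNames(out, levels(lab))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Concordance robustness under random pair subsets
#'
#' Draws `n_reps` random subsets of the pair set of size
#' `fraction * n_pairs` and records, per replicate, the mean
#' within-sample rho of each tissue group.
#'
#' @inheritParams within_sample_concordance
#' @param groups named group label per sample (same order as `samples`).
#' @param fraction fraction of pairs per subset, in (0, 1].
#' @param n_reps number of replicates.
#' @param seed RNG seed.
#' @return list with `rep_means` (n_reps x n_groups matrix), `summary`
#'   (per-group mean and SD over replicates) and `full` (the full-set
#'   group means).
#' @export
subset_robustness <- function(protein, mrna, pair_set, samples, groups,
                              fraction = 0.5, n_reps = 100L, seed = 1L,
                              min_pairs = 30L) {
  if (fraction <= 0 || fraction > 1) stop("fraction must be in (0, 1]")
  n_take <- round(fraction * nrow(pair_set))
  if (n_take < min_pairs)
    stop("fraction * n_pairs < ", min_pairs, "; subset too small")
  groups <- as.character(groups)
  glev <- sort(unique(groups))
  full_res <- within_sample_concordance(protein, mrna, pair_set, samples,
                                        min_pairs = min_pairs)
  full <- tapply(full_res$rho, groups, mean, na.rm = TRUE)[glev]
  set.seed(seed)
  rep_means <- matrix(NA_real_, n_reps, length(glev),
                      dimnames = list(NULL, glev))
  for (r in seq_len(n_reps)) {
    idx <- if (n_take == nrow(pair_set)) seq_len(nrow(pair_set))
           else sample(nrow(pair_set), n_take)
    ps <- pair_set[idx, , drop = FALSE]
    class(ps) <- class(pair_set)
    res <- within_sample_concordance(protein, mrna, ps, samples,
                                     min_pairs = min_pairs)
    rep_means[r, ] <- tapply(res$rho, groups, mean, na.rm = TRUE)[glev]
  }
  list(rep_means = rep_means,
       summary = data.frame(group = glev, mean = colMeans(rep_means),
                            sd = apply(rep_means, 2L, stats::sd)),
       full = full)
}

#' Covariate-adjusted association between two per-sample variables
#'
#' Ordinary least squares of `response` on `predictor` plus covariates
#' (factors expanded to indicators), reporting the predictor coefficient
#' with its SE and p-value, and the partial (covariate-residualized)
#' Pearson correlation between response and predictor.
#'
#' @param response,predictor numeric vectors per sample.
#' @param covariates data.frame of per-sample covariates (may be NULL).
#' @return list with `coefficient`, `se`, `p`, `adjusted_correlation`,
#'   `n_used`.
#' @export
adjusted_association <- function(response, predictor, covariates = NULL) {
  df <- data.frame(.y = response, .x = predictor)
  if (!is.null(covariates)) {
    stopifnot(nrow(covariates) == length(response))
    covariates <- as.data.frame(covariates)
    for (nm in names(covariates))
      if (is.character(covariates[[nm]]))
        covariates[[nm]] <- factor(covariates[[nm]])
    df <- cbind(df, covariates)
  }
  df <- df[stats::complete.cases(df), , drop = FALSE]
  p_cov <- ncol(df) - 2L
  if (nrow(df) < p_cov + 3L) stop("too few complete cases")
  fit <- stats::lm(.y ~ ., data = df)
  if (any(is.na(stats::coef(fit)))) {
    bad <- names(stats::coef(fit))[is.na(stats::coef(fit))]
    stop("collinear covariate(s): ", paste(bad, collapse = ", "))
  }
  sm <- summary(fit)$coefficients
  if (p_cov > 0) {
    cf <- df[, -(1:2), drop = FALSE]
    ry <- stats::resid(stats::lm(.y ~ ., data = cbind(df[".y"], cf)))
    rx <- stats::resid(stats::lm(.x ~ ., data = cbind(df[".x"], cf)))
    pc <- stats::cor(ry, rx)
  } else {
    pc <- stats::cor(df$.y, df$.x)
  }
  list(coefficient = sm[".x", "Estimate"], se = sm[".x", "Std. Error"],
       p = sm[".x", "Pr(>|t|)"], adjusted_correlation = pc,
       n_used = nrow(df))
}
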