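#' Filter a spectral-count matrix
#'
#' Two rules, applied in order.  (1) Peptide-support rule: drop proteins
#' whose maximum number of uniquely mapping peptides over all samples never
#' reaches `min_unique_peptides` (skipped when no support table is given).
#' (2) Coverage rule: drop proteins detected (count > 0) in fewer than
#' `ceiling(min_coverage_fraction * n_samples)` samples.
#'
#' @param counts an `omics_matrix` of kind `"counts"`.
#' @param peptide_support optional named numeric vector or two-column
#'   data.frame (`feature_id`, `max_unique_peptides`) giving, per protein,
#'   the maximum number of unique peptides observed in any one sample.
#' @param min_unique_peptides minimum unique-peptide support (default 2).
#' @param min_coverage_fraction detection fraction cutoff (default 0.10).
#' @return list with `matrix` (the filtered `omics_matrix`) and `report`,
#'   a `filter_report` recording `n_input_features`,
#'   `n_removed_peptide_rule`, `n_removed_coverage` and `kept_ids`.
#' @export
filter_features <- function(counts, peptide_support = NULL,
                            min_unique_peptides = 2L,
                            min_coverage_fraction = 0.10) {
  stopifnot(inherits(counts, "omics_matrix"), counts$value_kind == "counts")
  if (min_coverage_fraction <= 0 || min_coverage_fraction > 1)
    stop("min_coverage_fraction must be in (0, 1]")
  n_in <- length(counts$feature_ids)
  keep <- counts$feature_ids
  n_pep <- 0L
  if (!is.null(peptide_support)) {
    if (is.data.frame(peptide_support)) {
      ps <- stats::setNames(peptide_support[[2L]],
                            as.character(peptide_support[[1L]]))
    } else ps <- peptide_support
    sup <- ps[keep]
    sup[is.na(sup)] <- 0
    drop1 <- keep[sup < min_unique_peptides]
    n_pep <- length(drop1)
    keep <- setdiff(keep, drop1)
  }
  n_samp <- length(counts$sample_ids)
  need <- ceiling(min_coverage_fraction * n_samp)
  det <- rowSums(counts$values[keep, , drop = FALSE] > 0)
  drop2 <- keep[det < need]
  n_cov <- length(drop2)
  keep <- setdiff(keep, drop2)
  if (!length(keep))
    stop("no features pass the filters; relax min_unique_peptides or ",
         "min_coverage_fraction")
  report <- structure(list(n_input_features = n_in,
                           n_removed_peptide_rule = n_pep,
                           n_removed_coverage = n_cov,
                           kept_ids = keep,
                           min_unique_peptides = min_unique_peptides,
                           min_coverage_fraction = min_coverage_fraction,
                           min_detected_samples = need),
                      class = "filter_report")
  list(matrix = subset_omics(counts, features = keep), report = report)
}

#' @export
print.filter_report <- function(x, ...) {
  cat(sprintf(paste0("<filter_report> %d features in; %d removed by peptide",
                     " rule, %d by coverage (< %d samples); %d kept\n"),
              x$n_input_features, x$n_removed_peptide_rule,
              x$n_removed_coverage, x$min_detected_samples,
              length(x$kept_ids)))
  invisible(x)
}

#' Median-of-ratios size factors
#'
#' Per-sample scaling factors: each sample's factor is the median, over
#' features whose geometric mean across samples is positive, of the ratio
#' of the observed count to that geometric mean.  Factors are rescaled to
#' have geometric mean 1.
#'
#' @param counts an `omics_matrix` of kind `"counts"` with >= 2 samples.
#' @return named numeric vector of positive size factors (class
#'   `size_factors`).
#' @export
size_factors <- function(counts) {
  stopifnot(inherits(counts, "omics_matrix"), counts$value_kind == "counts")
  v <- counts$values
  if (ncol(v) < 2L) stop("need at least 2 samples")
  pos <- rowSums(v > 0) == ncol(v)
  if (!any(pos))
    stop("no feature has positive counts in every sample; cannot estimate ",
         "size factors")
  logg <- rowMeans(log(v[pos, , drop = FALSE]))
  f <- apply(v[pos, , drop = FALSE], 2L, function(col)
    exp(stats::median(log(col) - logg)))
  f <- f / exp(mean(log(f)))
  if (any(!is.finite(f) | f <= 0)) stop("non-finite size factor")
  structure(stats::setNames(f, counts$sample_ids), class = "size_factors")
}

#' Regularized log transform of counts
#'
#' A variance-stabilizing shrinkage transform in the spirit of the
#' regularized log: each value is a weighted combination of the sample's
#' own log count and the feature's across-sample mean,
#' `y = w * log2(count/sf + 0.5) + (1 - w) * log2(mean + 0.5)` with
#' `w = mean / (mean + prior_strength)` and `mean` the across-sample mean
#' normalized count.  Low-count features are pulled toward their mean,
#' removing the inflation of log-scale variance at low means.  This is an
#' explicit empirical-Bayes formula, not a re-implementation of any
#' package's rlog; only the variance-stabilization contract is claimed.
#'
#' @param counts an `omics_matrix` of kind `"counts"`.
#' @param factors size factors from [size_factors()] (or any positive
#'   per-sample vector).
#' @param prior_strength shrinkage prior in count units (default 5).
#' @return an `omics_matrix` of kind `"transformed"`.
#' @export
rlog_like <- function(counts, factors, prior_strength = 5) {
  stopifnot(inherits(counts, "omics_matrix"), counts$value_kind == "counts")
  if (prior_strength <= 0) stop("prior_strength must be positive")
  f <- as.numeric(factors)
  if (length(f) != length(counts$sample_ids))
    stop("one size factor per sample required")
  norm <- sweep(counts$values, 2L, f, "/")
  mu <- rowMeans(norm)
  w <- mu / (mu + prior_strength)
  y <- w * log2(norm + 0.5) + (1 - w) * log2(mu + 0.5)
  omics_matrix(y, counts$feature_ids, counts$sample_ids, "transformed")
}

# Negative-binomial log-linear IRLS for one feature.
# Model: y ~ NB(mu, size = 1/alpha), log mu = off + X beta.
# Returns beta, se of the last coefficient, convergence flag.
.nb_irls <- function(y, X, off, alpha, max_iter = 25L, tol = 1e-8) {
  beta <- rep(0, ncol(X))
  beta[1L] <- log(mean(y) + 0.1) - mean(off)
  for (it in seq_len(max_iter)) {
    eta <- off + drop(X %*% beta)
    eta <- pmin(pmax(eta, -30), 30)
    mu <- exp(eta)
    W <- mu / (1 + alpha * mu)
    z <- (y - mu) / mu
    XtW <- t(X * W)
    Fmat <- XtW %*% X
    sc <- drop(t(X) %*% (W * z))
    step <- tryCatch(solve(Fmat, sc), error = function(e) NULL)
    if (is.null(step)) return(list(beta = beta, se = NA_real_, ok = FALSE))
    beta_new <- beta + step
    if (max(abs(step)) < tol) { beta <- beta_new; break }
    beta <- beta_new
  }
  eta <- pmin(pmax(off + drop(X %*% beta), -30), 30)
  mu <- exp(eta)
  W <- mu / (1 + alpha * mu)
  Fmat <- t(X * W) %*% X
  cov <- tryCatch(solve(Fmat), error = function(e) NULL)
  if (is.null(cov)) return(list(beta = beta, se = NA_real_, ok = FALSE))
  list(beta = beta, se = sqrt(diag(cov))[ncol(X)], ok = TRUE)
}

#' Negative-binomial Wald test for tumor-vs-normal differential abundance
#'
#' Per feature: a negative-binomial log-linear model with an offset of
#' log size factor and a single group coefficient.  The dispersion is
#' estimated per feature by method of moments on normalized counts
#' (floored at 1e-8) and shrunk half-way, on the log scale, toward a
#' log-linear mean-dispersion trend fitted across features.  Wald
#' z = beta / SE with a two-sided normal p-value; BH q-values are computed
#' over features that pass independent filtering (mean normalized count
#' >= `min_mean_filter`); filtered and all-zero features get `q = NA`.
#'
#' @param counts an `omics_matrix` of kind `"counts"`.
#' @param factors size factors.
#' @param groups character/factor per sample with levels `normal`, `tumor`
#'   (fold changes are tumor over normal).
#' @param min_mean_filter independent-filter threshold on the mean
#'   normalized count (default 1).
#' @return a `data.frame` (class `differential_result`) with one row per
#'   feature: `feature_id`, `log2fc`, `stat` (Wald z), `p`, `q`,
#'   `direction`, `dispersion`, `base_mean`.
#' @export
nb_wald <- function(counts, factors, groups, min_mean_filter = 1) {
  stopifnot(inherits(counts, "omics_matrix"), counts$value_kind == "counts")
  groups <- as.character(groups)
  if (length(groups) != length(counts$sample_ids))
    stop("one group label per sample required")
  is_t <- groups == "tumor"
  if (!any(is_t) || all(is_t)) stop("both groups must be non-empty")
  f <- as.numeric(factors)
  v <- counts$values
  norm <- sweep(v, 2L, f, "/")
  base_mean <- rowMeans(norm)
  # method-of-moments dispersion on normalized counts, pooled within groups
  mom_disp <- apply(norm, 1L, function(q) {
    m1 <- mean(q[is_t]); m0 <- mean(q[!is_t])
    resid2 <- c((q[is_t] - m1)^2, (q[!is_t] - m0)^2)
    vhat <- sum(resid2) / (length(q) - 2L)
    mbar <- mean(q)
    if (mbar <= 0) return(NA_real_)
    max((vhat - mbar) / mbar^2, 1e-8)
  })
  # log-linear mean-dispersion trend, then 50/50 shrinkage on the log scale
  ok_tr <- !is.na(mom_disp) & mom_disp > 1e-8 & base_mean > 0
  if (sum(ok_tr) >= 10L) {
    fit <- stats::lm(log(mom_disp[ok_tr]) ~ log(base_mean[ok_tr]))
    trend <- exp(stats::coef(fit)[1L] + stats::coef(fit)[2L] * log(pmax(base_mean, 1e-8)))
  } else {
    trend <- rep(exp(mean(log(mom_disp[ok_tr]))), length(mom_disp))
  }
  disp <- exp(0.5 * log(pmax(mom_disp, 1e-8)) + 0.5 * log(pmax(trend, 1e-8)))
  disp[is.na(mom_disp)] <- trend[is.na(mom_disp)]
  disp <- pmax(disp, 1e-8)
  X <- cbind(1, as.numeric(is_t))
  off <- log(f)
  n_feat <- nrow(v)
  log2fc <- stat <- p <- rep(NA_real_, n_feat)
  for (g in seq_len(n_feat)) {
    y <- v[g, ]
    if (all(y == 0)) next
    fit <- .nb_irls(y, X, off, disp[g])
    if (!fit$ok || !is.finite(fit$se) || fit$se <= 0) next
    log2fc[g] <- fit$beta[2L] / log(2)
    stat[g] <- fit$beta[2L] / fit$se
    p[g] <- 2 * stats::pnorm(-abs(stat[g]))
  }
  q <- rep(NA_real_, n_feat)
  in_family <- !is.na(p) & base_mean >= min_mean_filter
  q[in_family] <- bh_adjust(p[in_family])
  res <- data.frame(feature_id = counts$feature_ids, log2fc = log2fc,
                    stat = stat, p = p, q = q,
                    direction = ifelse(is.na(log2fc), NA_character_,
                                       ifelse(log2fc > 0, "up", "down")),
                    dispersion = disp, base_mean = base_mean,
                    stringsAsFactors = FALSE)
  class(res) <- c("differential_result", "data.frame")
  res
}

#' Paired signed-rank differential test
#'
#' Per feature: a two-sided Wilcoxon signed-rank test on the
#' tumor-minus-normal differences of transformed values over complete
#' tissue pairs (zeros dropped), with the median paired log2 fold change.
#'
#' @param values an `omics_matrix` of kind `"transformed"` or
#'   `"log_intensity"`.
#' @param clinical a `sample_table` with `tissue` and `pair_id` columns; a
#'   pair is complete when both its tumor and normal sample are columns of
#'   `values`.
#' @return a `differential_result` data.frame with `feature_id`, `log2fc`
#'   (median paired difference), `stat` (W), `p`, `q`, `direction`,
#'   `n_pairs`.
#' @export
paired_signed_rank <- function(values, clinical) {
  stopifnot(inherits(values, "omics_matrix"))
  cl <- clinical[!is.na(clinical$pair_id) & clinical$pair_id != "", ]
  tum <- cl[cl$tissue == "tumor", c("sample_id", "pair_id")]
  nor <- cl[cl$tissue == "normal", c("sample_id", "pair_id")]
  common <- intersect(tum$pair_id, nor$pair_id)
  tum_id <- tum$sample_id[match(common, tum$pair_id)]
  nor_id <- nor$sample_id[match(common, nor$pair_id)]
  keep <- tum_id %in% values$sample_ids & nor_id %in% values$sample_ids
  tum_id <- tum_id[keep]; nor_id <- nor_id[keep]
  if (length(tum_id) < 6L) stop("need at least 6 complete tissue pairs")
  d_mat <- values$values[, tum_id, drop = FALSE] -
    values$values[, nor_id, drop = FALSE]
  res_list <- apply(d_mat, 1L, function(d) {
    d <- d[!is.na(d)]
    t_ <- signed_rank_test(d)
    c(lfc = if (length(d)) stats::median(d) else NA_real_,
      stat = t_$statistic, p = t_$p, n = t_$n_used)
  })
  res <- data.frame(feature_id = values$feature_ids,
                    log2fc = res_list["lfc", ], stat = res_list["stat", ],
                    p = res_list["p", ], q = bh_adjust(res_list["p", ]),
                    direction = ifelse(res_list["lfc", ] > 0, "up", "down"),
                    n_pairs = as.integer(res_list["n", ]),
                    stringsAsFactors = FALSE)
  rownames(res) <- NULL
  class(res) <- c("differential_result", "data.frame")
  res
}
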