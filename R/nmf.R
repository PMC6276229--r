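#' Select high-variability features by median absolute deviation
#'
#' Keeps features with (unscaled) MAD at or above `mad_cutoff`, then the
#' `top_n` of those by MAD (descending, feature-id tiebreak).
#'
#' @param x an `omics_matrix` (transformed values).
#' @param mad_cutoff minimum median absolute deviation from the median
#'   (default 0.5, unscaled: no consistency constant).
#' @param top_n maximum number of features kept (default 1000).
#' @return an `omics_matrix` restricted to the selected features.
#' @export
select_variable <- function(x, mad_cutoff = 0.5, top_n = 1000L) {
  stopifnot(inherits(x, "omics_matrix"))
  mads <- apply(x$values, 1L, function(v)
    stats::median(abs(v - stats::median(v, na.rm = TRUE)), na.rm = TRUE))
  pass <- which(mads >= mad_cutoff)
  if (!length(pass)) stop("no feature passes the MAD cutoff")
  ord <- pass[order(-mads[pass], x$feature_ids[pass])]
  keep <- ord[seq_len(min(top_n, length(ord)))]
  subset_omics(x, features = x$feature_ids[keep])
}

# generalized KL divergence D(V || WH), with 0 log 0 = 0
.kl_div <- function(V, WH) {
  pos <- V > 0
  sum(V[pos] * log(V[pos] / WH[pos])) - sum(V) + sum(WH)
}

#' Non-negative matrix factorization by multiplicative KL updates
#'
#' Brunet-style multiplicative updates minimizing the generalized
#' Kullback-Leibler divergence D(V || WH) from a seeded random uniform
#' initialization.  Stops when the relative objective change falls below
#' `tol` or after `max_iter` iterations.  The objective trace is
#' non-increasing by construction of the updates.
#'
#' @param V non-negative numeric matrix (features x samples) without
#'   all-zero rows or columns; typically `log2(normalized count + 1)`.
#' @param K factorization rank, 2 <= K < min(dim(V)) (K = 1 allowed for
#'   degenerate checks).
#' @param seed RNG seed for the initialization.
#' @param max_iter iteration cap (default 500).
#' @param tol relative objective-change stopping tolerance (default
#'   1e-6).
#' @return an `nmf_result` list: `K`, `W` (features x K), `H` (K x
#'   samples), `objective` (trace), `seed`, `iterations`.
#' @export
nmf_factorize <- function(V, K, seed = 1L, max_iter = 500L, tol = 1e-6) {
  V <- as.matrix(V)
  if (any(V < 0)) stop("V must be non-negative")
  if (any(rowSums(V) == 0)) stop("all-zero row in V; remove it first")
  if (any(colSums(V) == 0)) stop("all-zero column in V; remove it first")
  if (K < 1L || (K > 1L && K >= min(dim(V)))) stop("invalid K")
  n <- nrow(V); m <- ncol(V)
  set.seed(seed)
  W <- matrix(stats::runif(n * K, 0.1, 1), n, K)
  H <- matrix(stats::runif(K * m, 0.1, 1), K, m)
  eps <- .Machine$double.eps
  obj <- numeric(0)
  prev <- Inf
  for (it in seq_len(max_iter)) {
    WH <- W %*% H + eps
    H <- H * (t(W) %*% (V / WH)) / pmax(colSums(W), eps)
    WH <- W %*% H + eps
    W <- W * ((V / WH) %*% t(H)) / rep(pmax(rowSums(H), eps), each = n)
    d <- .kl_div(V, W %*% H + eps)
    obj <- c(obj, d)
    if (is.finite(prev) && abs(prev - d) <= tol * max(abs(prev), 1)) break
    prev <- d
  }
  structure(list(K = K, W = W, H = H, objective = obj, seed = seed,
                 iterations = length(obj)), class = "nmf_result")
}

#' Consensus NMF clustering with cophenetic rank selection
#'
#' For each K in `k_min:k_max`: `n_restarts` factorizations from
#' distinct seeds (derived deterministically from `seed`); each run's
#' hard assignment is the argmax row of H per sample; the consensus
#' matrix is the mean sample-by-sample connectivity over restarts.  The
#' cophenetic coefficient of each K is the Pearson correlation between
#' the consensus dissimilarity (1 - consensus) and the cophenetic
#' distances of its average-linkage dendrogram; the selected K maximizes
#' it, and the final assignment cuts that dendrogram into K clusters.
#'
#' @param V non-negative matrix (see [nmf_factorize()]).
#' @param k_min,k_max rank range (defaults 2 and 7); `k_max` must be
#'   below the number of samples.
#' @param n_restarts restarts per K (>= 10, default 30).
#' @param seed master seed.
#' @param max_iter,tol per-run NMF controls.
#' @return a `consensus_result` list: `consensus` (list of per-K
#'   matrices), `cophenetic` (named per-K), `selected_k`, `assignment`
#'   (named integer vector), `objective_traces` (list of per-run traces
#'   at the selected K).
#' @export
consensus_cluster <- function(V, k_min = 2L, k_max = 7L, n_restarts = 30L,
                              seed = 1L, max_iter = 300L, tol = 1e-5) {
  V <- as.matrix(V)
  if (n_restarts < 10L) stop("n_restarts must be >= 10")
  if (k_max >= ncol(V)) stop("k_max must be below the number of samples")
  ks <- k_min:k_max
  samples <- colnames(V)
  m <- ncol(V)
  consensus <- list()
  coph <- stats::setNames(numeric(length(ks)), as.character(ks))
  traces <- list()
  for (K in ks) {
    Cmat <- matrix(0, m, m)
    run_traces <- list()
    for (r in seq_len(n_restarts)) {
      run_seed <- (seed * 1000L + K * 100L + r) %% .Machine$integer.max
      fit <- nmf_factorize(V, K, seed = run_seed, max_iter = max_iter,
                           tol = tol)
      cl <- apply(fit$H, 2L, which.max)
      Cmat <- Cmat + outer(cl, cl, "==")
      run_traces[[r]] <- fit$objective
    }
    Cmat <- Cmat / n_restarts
    diag(Cmat) <- 1
    dimnames(Cmat) <- list(samples, samples)
    consensus[[as.character(K)]] <- Cmat
    d <- stats::as.dist(1 - Cmat)
    hc <- stats::hclust(d, method = "average")
    cd <- stats::cophenetic(hc)
    coph[as.character(K)] <- if (stats::sd(d) == 0 || stats::sd(cd) == 0) 1
      else stats::cor(d, cd)
    traces[[as.character(K)]] <- run_traces
  }
  sel <- ks[which.max(coph)]
  hc <- stats::hclust(stats::as.dist(1 - consensus[[as.character(sel)]]),
                      method = "average")
  assignment <- stats::cutree(hc, k = sel)
  structure(list(consensus = consensus, cophenetic = coph,
                 selected_k = sel, assignment = assignment,
                 objective_traces = traces[[as.character(sel)]]),
            class = "consensus_result")
}

#' Association between cluster assignment and a binary label
#'
#' Builds the 2x2 group-by-label contingency table and applies
#' [fisher_exact()].
#'
#' @param assignments named vector of cluster labels (2 distinct values).
#' @param label named binary (0/1 or logical) annotation per sample.
#' @return a `fisher_result` as returned by [fisher_exact()], plus the
#'   group/label level names.
#' @export
associate_groups <- function(assignments, label) {
  common <- intersect(names(assignments), names(label))
  if (length(common) < 4L) stop("too few samples shared between inputs")
  a <- factor(assignments[common])
  l <- factor(as.integer(as.logical(label[common])), levels = 0:1)
  if (nlevels(a) != 2L) stop("need exactly 2 cluster groups")
  if (any(table(a) == 0L)) stop("a cluster group is empty")
  tab <- table(a, l)
  res <- fisher_exact(matrix(as.integer(tab), 2L, 2L))
  res$groups <- levels(a)
  res$labels <- levels(l)
  res
}

#' Adjusted Rand index between two partitions
#'
#' @param a,b integer/factor vectors of equal length.
#' @return the adjusted Rand index (1 for identical partitions up to
#'   relabeling).
#' @export
adjusted_rand_index <- function(a, b) {
  if (length(a) != length(b)) stop("partitions must have equal length")
  tab <- table(a, b)
  n <- length(a)
  sum_ij <- sum(choose(tab, 2))
  sum_a <- sum(choose(rowSums(tab), 2))
  sum_b <- sum(choose(colSums(tab), 2))
  expected <- sum_a * sum_b / choose(n, 2)
  max_idx <- (sum_a + sum_b) / 2
  if (max_idx == expected) return(1)
  (sum_ij - expected) / (max_idx - expected)
}

#' Log-normalized NMF input from counts
#'
#' `log2(count / size_factor + 1)`: non-negative by construction, the
#' conventional input scale for factorizing normalized spectral counts.
#'
#' @param counts an `omics_matrix` of kind `"counts"`.
#' @param factors size factors from [size_factors()].
#' @return an `omics_matrix` of kind `"transformed"`.
#' @export
nmf_input <- function(counts, factors) {
  stopifnot(inherits(counts, "omics_matrix"), counts$value_kind == "counts")
  v <- log2(sweep(counts$values, 2L, as.numeric(factors), "/") + 1)
  omics_matrix(v, counts$feature_ids, counts$sample_ids, "transformed")
}
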