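#' Pre-ranked enrichment score (weighted Kolmogorov-Smirnov)
#'
#' The classic GSEA-style running sum over a ranked list: at each member
#' of the set ("hit") the sum increases by |stat|^weight_p normalized by
#' the set's total; at each non-member it decreases by 1/(N - set size).
#' ES is the deviation of maximal magnitude; the leading edge contains
#' the set members at or before the ES position (positive ES) or at or
#' after it (negative ES).
#'
#' @param stats_ranked named numeric vector, features as names, sorted in
#'   decreasing statistic order (it is re-sorted defensively).
#' @param set character vector of set member ids.
#' @param weight_p hit-weight exponent (default 1; 0 gives the unweighted
#'   KS statistic).
#' @return list with `es`, `leading_edge`, `n_hits`, `running` (the full
#'   running-sum vector, for callers that need it).
#' @export
preranked_es <- function(stats_ranked, set, weight_p = 1) {
  if (is.null(names(stats_ranked))) stop("stats_ranked must be named")
  if (anyDuplicated(names(stats_ranked))) stop("duplicate features in ranking")
  s <- sort(stats_ranked, decreasing = TRUE)
  hit <- names(s) %in% set
  if (!any(hit)) stop("set has no members in the ranked list")
  N <- length(s)
  n_hit <- sum(hit)
  w <- abs(s)^weight_p
  w[!hit] <- 0
  tot <- sum(w)
  inc <- if (tot > 0) w / tot else as.numeric(hit) / n_hit
  if (N == n_hit) {
    dec <- rep(0, N)  # degenerate: set covers the whole list
  } else {
    dec <- as.numeric(!hit) / (N - n_hit)
  }
  running <- unname(cumsum(inc - dec))
  i_max <- which.max(abs(running))
  es <- running[i_max]
  le <- if (es >= 0) names(s)[seq_len(i_max)][hit[seq_len(i_max)]]
        else names(s)[i_max:N][hit[i_max:N]]
  list(es = es, leading_edge = le, n_hits = n_hit, running = running)
}

#' Pre-ranked permutation enrichment over a gene-set collection
#'
#' Computes the weighted-KS enrichment score for each eligible set, then
#' builds a null by permuting the feature labels of the ranked list
#' `n_perm` times (equivalently: re-drawing random sets of the same
#' size).  NES is the ES divided by the mean |null ES| of the same sign;
#' the empirical p-value is one-sided by ES sign with the +1 correction;
#' BH q-values are computed across sets.  Deterministic given `seed`.
#'
#' @param stats_ranked named numeric vector of per-feature statistics.
#' @param collection a [gene_set_collection()].
#' @param n_perm number of permutations (>= 100, default 1000).
#' @param seed RNG seed.
#' @param weight_p hit-weight exponent (default 1).
#' @param min_size,max_size set-size eligibility bounds after mapping to
#'   the ranked list (defaults 10 and 500).
#' @return an `enrichment_result` data.frame: `set`, `size_used`,
#'   `n_unmapped`, `es`, `nes`, `p`, `q`, `leading_edge` (comma-joined).
#' @export
preranked_enrichment <- function(stats_ranked, collection, n_perm = 1000L,
                                 seed = 1L, weight_p = 1,
                                 min_size = 10L, max_size = 500L) {
  stopifnot(inherits(collection, "gene_set_collection"))
  if (n_perm < 100L) stop("n_perm must be >= 100")
  s <- sort(stats_ranked, decreasing = TRUE)
  feats <- names(s)
  mapped <- lapply(collection$sets, intersect, feats)
  size <- lengths(mapped)
  elig <- size >= min_size & size <= max_size
  if (!any(elig)) stop("no gene set within the size bounds after mapping")
  sets <- mapped[elig]
  set.seed(seed)
  rows <- lapply(names(sets), function(nm) {
    obs <- preranked_es(s, sets[[nm]], weight_p)
    k <- length(sets[[nm]])
    null_es <- vapply(seq_len(n_perm), function(i)
      preranked_es(s, sample(feats, k), weight_p)$es, numeric(1))
    same <- null_es[sign(null_es) == sign(obs$es)]
    nes <- if (length(same)) obs$es / mean(abs(same)) else NA_real_
    p <- if (length(same))
      (1 + sum(abs(same) >= abs(obs$es))) / (1 + length(same)) else 1
    data.frame(set = nm, size_used = k,
               n_unmapped = length(collection$sets[[nm]]) - k,
               es = obs$es, nes = nes, p = p,
               leading_edge = paste(obs$leading_edge, collapse = ","),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$q <- bh_adjust(out$p)
  out <- out[, c("set", "size_used", "n_unmapped", "es", "nes", "p", "q",
                 "leading_edge")]
  rownames(out) <- NULL
  class(out) <- c("enrichment_result", "data.frame")
  out
}

#' Kolmogorov-Smirnov enrichment of gene sets in per-pair concordance
#'
#' For each set, a two-sample two-sided KS test of the across-subject
#' rho values of pairs whose gene is in the set versus all remaining
#' pairs.  D is reported signed: positive when the in-set median rho
#' exceeds the out-of-set median.  Sets mapping to fewer than `min_size`
#' pairs are skipped and recorded.  Results are ordered by q then |D|.
#'
#' @param per_pair a `concordance_result` from [per_pair_concordance()]
#'   (NA rho dropped).
#' @param collection a [gene_set_collection()] of gene ids.
#' @param min_size minimum mapped pairs per set (default 5).
#' @return an `enrichment_result` data.frame: `set`, `size_used`, `d`
#'   (signed), `p`, `q`, `skipped`.
#' @export
ks_concordance_enrichment <- function(per_pair, collection, min_size = 5L) {
  stopifnot(inherits(collection, "gene_set_collection"))
  ok <- !is.na(per_pair$rho)
  gene <- per_pair$gene_id[ok]
  rho <- per_pair$rho[ok]
  rows <- lapply(names(collection$sets), function(nm) {
    inset <- gene %in% collection$sets[[nm]]
    n_in <- sum(inset)
    if (n_in < min_size || n_in == length(rho))
      return(data.frame(set = nm, size_used = n_in, d = NA_real_,
                        p = NA_real_, skipped = TRUE,
                        stringsAsFactors = FALSE))
    x <- rho[inset]; y <- rho[!inset]
    kt <- suppressWarnings(stats::ks.test(x, y))
    d_sign <- if (stats::median(x) >= stats::median(y)) 1 else -1
    data.frame(set = nm, size_used = n_in,
               d = d_sign * unname(kt$statistic), p = kt$p.value,
               skipped = FALSE, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$q <- bh_adjust(out$p)
  out <- out[order(out$skipped, out$q, -abs(out$d)), ]
  out <- out[, c("set", "size_used", "d", "p", "q", "skipped")]
  rownames(out) <- NULL
  class(out) <- c("enrichment_result", "data.frame")
  out
}
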