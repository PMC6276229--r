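#' Midranks of a numeric vector
#'
#' Average ranks with ties sharing their midrank; the basis of the
#' tie-corrected Spearman coefficient.
#' @param x numeric vector without NA.
#' @return numeric vector of midranks.
#' @keywords internal
midranks <- function(x) {
  o <- order(x)
  r <- numeric(length(x))
  sx <- x[o]
  i <- 1L
  n <- length(x)
  while (i <= n) {
    j <- i
    while (j < n && sx[j + 1L] == sx[i]) j <- j + 1L
    r[o[i:j]] <- (i + j) / 2
    i <- j + 1L
  }
  r
}

#' Tie-corrected Spearman correlation
#'
#' Pearson correlation of midranks, the standard tie-corrected form of
#' Spearman's rho.  Pairs where either value is NA are dropped
#' (pairwise-complete).
#'
#' @param x,y numeric vectors of equal length.
#' @param min_n minimum number of complete pairs (default 3).
#' @return rho in \[-1, 1\], or NA with attribute `reason` when either
#'   vector is constant or fewer than `min_n` complete pairs remain.
#' @export
spearman_rho <- function(x, y, min_n = 3L) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < min_n)
    return(structure(NA_real_, reason = "insufficient_n"))
  rx <- midranks(x); ry <- midranks(y)
  sx <- stats::sd(rx); sy <- stats::sd(ry)
  if (sx == 0 || sy == 0)
    return(structure(NA_real_, reason = "constant_input"))
  sum((rx - mean(rx)) * (ry - mean(ry))) / ((length(x) - 1) * sx * sy)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up FDR adjustment over the non-NA entries; NA entries are preserved
#' and do not count toward the family size m.
#'
#' @param p numeric vector of p-values in \[0,1\] (NA allowed).
#' @return vector of q-values, same length and order as `p`.
#' @export
bh_adjust <- function(p) {
  q <- rep(NA_real_, length(p))
  ok <- which(!is.na(p))
  if (!length(ok)) return(q)
  pv <- p[ok]
  if (any(pv < 0 | pv > 1)) stop("p-values must lie in [0,1]")
  m <- length(pv)
  o <- order(pv, decreasing = TRUE)
  ro <- order(o)
  q[ok] <- pmin(1, cummin(pv[o] * m / seq(m, 1)))[ro]
  q
}

#' Two-sample Wilcoxon rank-sum test
#'
#' Two-sided.  Exact when both groups have at most 12 observations
#' (distribution-free enumeration via the Wilcoxon distribution when there
#' are no ties, full combination enumeration of midranks otherwise);
#' normal approximation with tie correction for larger samples.
#'
#' @param x,y numeric vectors (the two groups).
#' @return list with `statistic` (Mann-Whitney U for `x`), `p`, `method`.
#' @export
ranksum_test <- function(x, y) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  n1 <- length(x); n2 <- length(y)
  if (n1 < 1L || n2 < 1L) stop("both groups must be non-empty")
  r <- midranks(c(x, y))
  U <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  has_ties <- anyDuplicated(c(x, y)) > 0L
  if (n1 <= 12L && n2 <= 12L) {
    if (!has_ties) {
      # exact two-sided p from the null Wilcoxon distribution
      p <- 2 * min(stats::pwilcox(U, n1, n2),
                   1 - stats::pwilcox(U - 1, n1, n2))
      return(list(statistic = U, p = min(1, p), method = "exact"))
    }
    if (choose(n1 + n2, n1) <= 2e5) {
      # exact with ties: enumerate all group-1 position choices
      idx <- utils::combn(n1 + n2, n1)
      sums <- colSums(matrix(r[idx], nrow = n1))
      u_null <- sums - n1 * (n1 + 1) / 2
      eps <- 1e-9
      p <- 2 * min(mean(u_null <= U + eps), mean(u_null >= U - eps))
      return(list(statistic = U, p = min(1, p), method = "exact_ties"))
    }
  }
  mu <- n1 * n2 / 2
  n <- n1 + n2
  tie_tab <- table(c(x, y))
  tie_term <- sum(tie_tab^3 - tie_tab) / (n * (n - 1))
  sig2 <- n1 * n2 / 12 * (n + 1 - tie_term)
  if (sig2 <= 0) return(list(statistic = U, p = 1, method = "degenerate"))
  z <- (U - mu) / sqrt(sig2)
  list(statistic = U, p = min(1, 2 * stats::pnorm(-abs(z))),
       method = "normal_tie_corrected")
}

#' Wilcoxon signed-rank test on paired differences
#'
#' Two-sided; zero differences are dropped.  For 12 or fewer non-zero
#' differences the null is obtained by full enumeration of the 2^n sign
#' patterns on the midranks of |d| (exact even with ties); otherwise a
#' tie-corrected normal approximation is used.
#'
#' @param d numeric vector of paired differences.
#' @return list with `statistic` (W, sum of positive ranks), `p`, `n_used`,
#'   `method`; `p` is NA when all differences are zero.
#' @export
signed_rank_test <- function(d) {
  d <- d[!is.na(d)]
  d <- d[d != 0]
  n <- length(d)
  if (n == 0L)
    return(list(statistic = NA_real_, p = NA_real_, n_used = 0L,
                method = "all_zero"))
  r <- midranks(abs(d))
  W <- sum(r[d > 0])
  EW <- sum(r) / 2
  if (n <= 12L) {
    # 2^n sign patterns; ties in |d| handled exactly through midranks
    signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
    w_null <- as.vector(signs %*% r)
    eps <- 1e-9
    p <- 2 * min(mean(w_null <= W + eps), mean(w_null >= W - eps))
    return(list(statistic = W, p = min(1, p), n_used = n, method = "exact"))
  }
  sig2 <- sum(r^2) / 4
  if (sig2 <= 0)
    return(list(statistic = W, p = NA_real_, n_used = n, method = "degenerate"))
  z <- (W - EW) / sqrt(sig2)
  list(statistic = W, p = min(1, 2 * stats::pnorm(-abs(z))), n_used = n,
       method = "normal_tie_corrected")
}

#' Kruskal-Wallis test with tie correction
#'
#' @param values numeric vector of scores.
#' @param groups factor/character of the same length (>= 2 non-empty
#'   levels).
#' @return list with `statistic` (H), `df`, `p`.
#' @export
kruskal_wallis <- function(values, groups) {
  ok <- !is.na(values) & !is.na(groups)
  values <- values[ok]; groups <- factor(as.character(groups[ok]))
  k <- nlevels(groups)
  if (k < 2L) stop("need at least 2 groups")
  n <- length(values)
  r <- midranks(values)
  H <- 12 / (n * (n + 1)) *
    sum(tapply(r, groups, function(ri) length(ri) * (mean(ri) - (n + 1) / 2)^2))
  tie_tab <- table(values)
  C <- 1 - sum(tie_tab^3 - tie_tab) / (n^3 - n)
  if (C > 0) H <- H / C
  list(statistic = H, df = k - 1L,
       p = stats::pchisq(H, df = k - 1L, lower.tail = FALSE))
}

#' Fisher's exact test on a 2x2 table
#'
#' Two-sided p-value as the sum of hypergeometric probabilities of tables
#' (at fixed margins) no more probable than the observed one; odds ratio is
#' the sample odds ratio, with a 0.5 continuity correction applied to every
#' cell when any cell is zero.
#'
#' @param tab 2x2 matrix of non-negative integer counts with positive
#'   margins.
#' @return list with `table`, `odds_ratio`, `p`.
#' @export
fisher_exact <- function(tab) {
  tab <- as.matrix(tab)
  if (!all(dim(tab) == c(2L, 2L))) stop("table must be 2x2")
  if (any(tab < 0) || any(tab != round(tab)))
    stop("counts must be non-negative integers")
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    stop("table has a zero margin")
  m <- sum(tab[1, ]); n <- sum(tab[2, ]); kk <- sum(tab[, 1])
  x <- tab[1, 1]
  support <- max(0, kk - n):min(kk, m)
  d <- stats::dhyper(support, m, n, kk)
  p <- sum(d[d <= d[support == x] * (1 + 1e-7)])
  ct <- if (any(tab == 0)) tab + 0.5 else tab
  or <- (ct[1, 1] * ct[2, 2]) / (ct[1, 2] * ct[2, 1])
  list(table = tab, odds_ratio = or, p = min(1, p))
}
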