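#' The 11-gene cell-cycle proliferation metagene
#'
#' The standard marker list used to score tissue proliferation from
#' array-based expression.
#' @format character vector of 11 gene symbols.
#' @export
proliferation_gene_list <- c("BIRC5", "CCNB1", "CDC20", "CEP55", "MKI67",
                             "NDC80", "NUF2", "PTTG1", "RRM2", "TYMS",
                             "UBE2C")

#' Proliferation metagene score
#'
#' Per-sample sum of the listed genes' log2 expression values; with
#' `standardize = TRUE` (default) each gene is z-scored across samples
#' before summing, making the score robust to per-gene scale.  Listed
#' genes absent from the matrix are reported, not an error (unless all
#' are absent).
#'
#' @param mrna an `omics_matrix` of log2 expression.
#' @param gene_list character vector of marker genes (default the 11-gene
#'   cell-cycle list).
#' @param standardize z-score each gene across samples first (default
#'   TRUE).
#' @return a `metagene_score` list: `score` (named per-sample vector),
#'   `genes_used`, `genes_missing`, `standardized`.
#' @export
proliferation_score <- function(mrna, gene_list = proliferation_gene_list,
                                standardize = TRUE) {
  stopifnot(inherits(mrna, "omics_matrix"))
  used <- intersect(gene_list, mrna$feature_ids)
  missing <- setdiff(gene_list, mrna$feature_ids)
  if (!length(used)) stop("none of the listed genes is in the mRNA matrix")
  v <- mrna$values[used, , drop = FALSE]
  if (standardize) {
    v <- t(scale(t(v)))
    v[is.nan(v)] <- 0  # constant gene contributes nothing
  }
  list(score = stats::setNames(colSums(v), mrna$sample_ids),
       genes_used = used, genes_missing = missing,
       standardized = standardize)
}

#' Stratify tumors into concordance groups
#'
#' Cuts per-tumor concordance scores at empirical quantiles (linear
#' interpolation convention): strictly below the lower quantile is
#' `low`, strictly above the upper quantile is `high`, everything else
#' -- including scores tied with a boundary -- is `mid`.
#'
#' @param scores named numeric vector of per-tumor scores (>= 8 non-NA).
#' @param lower_q,upper_q quantile cut points (defaults 0.25 / 0.75).
#' @return named factor with levels `low`, `mid`, `high`.
#' @export
concordance_groups <- function(scores, lower_q = 0.25, upper_q = 0.75) {
  s <- scores[!is.na(scores)]
  if (length(s) < 8L) stop("need at least 8 scored tumors")
  if (length(unique(s)) == 1L) stop("all scores identical; cannot stratify")
  qs <- stats::quantile(s, c(lower_q, upper_q), type = 7)
  g <- ifelse(s < qs[1L], "low", ifelse(s > qs[2L], "high", "mid"))
  factor(stats::setNames(g, names(s)), levels = c("low", "mid", "high"))
}

#' Kaplan-Meier product-limit estimate
#'
#' @param times positive event/censoring times.
#' @param events 0/1 event indicators.
#' @param groups group label per subject (a single group if NULL).
#' @return a `survival_fit` list with `model = "km"` and `curves`, a
#'   data.frame with `group`, `time`, `n_risk`, `n_event`, `survival`
#'   (one row per distinct event time plus the time-0 anchor).
#' @export
km_estimate <- function(times, events, groups = NULL) {
  if (any(times <= 0)) stop("times must be positive")
  if (!all(events %in% 0:1)) stop("events must be 0/1")
  if (is.null(groups)) groups <- rep("all", length(times))
  groups <- as.character(groups)
  curves <- lapply(sort(unique(groups)), function(g) {
    t_ <- times[groups == g]; e_ <- events[groups == g]
    if (!length(t_)) stop("empty group '", g, "'")
    ev_times <- sort(unique(t_[e_ == 1]))
    s <- 1
    rows <- list(data.frame(group = g, time = 0, n_risk = length(t_),
                            n_event = 0L, survival = 1))
    for (tt in ev_times) {
      n_risk <- sum(t_ >= tt)
      d <- sum(t_ == tt & e_ == 1)
      s <- s * (1 - d / n_risk)
      rows[[length(rows) + 1L]] <- data.frame(group = g, time = tt,
                                              n_risk = n_risk, n_event = d,
                                              survival = s)
    }
    do.call(rbind, rows)
  })
  structure(list(model = "km", curves = do.call(rbind, curves)),
            class = "survival_fit")
}

#' Log-rank test
#'
#' The standard observed-minus-expected chi-square over the pooled event
#' times with hypergeometric variance, on k - 1 degrees of freedom.
#'
#' @inheritParams km_estimate
#' @return a `survival_fit` list with `model = "logrank"`, `statistic`,
#'   `df`, `p`, `observed`, `expected`.
#' @export
logrank_test <- function(times, events, groups) {
  groups <- factor(as.character(groups))
  k <- nlevels(groups)
  if (k < 2L) stop("need at least 2 groups")
  if (sum(events) < 1L) stop("no events")
  ev_times <- sort(unique(times[events == 1]))
  O <- E <- numeric(k)
  V <- matrix(0, k, k)
  for (tt in ev_times) {
    at_risk <- times >= tt
    n <- sum(at_risk)
    d <- sum(times == tt & events == 1)
    n_g <- tabulate(groups[at_risk], nbins = k)
    d_g <- tabulate(groups[times == tt & events == 1], nbins = k)
    O <- O + d_g
    E <- E + d * n_g / n
    if (n > 1) {
      p_g <- n_g / n
      Vt <- d * (n - d) / (n - 1) * (diag(p_g, k) - outer(p_g, p_g))
      V <- V + Vt
    }
  }
  idx <- seq_len(k - 1L)
  om <- (O - E)[idx]
  Vi <- tryCatch(solve(V[idx, idx, drop = FALSE]), error = function(e) NULL)
  stat <- if (is.null(Vi)) 0 else drop(t(om) %*% Vi %*% om)
  structure(list(model = "logrank", statistic = stat, df = k - 1L,
                 p = stats::pchisq(stat, k - 1L, lower.tail = FALSE),
                 observed = stats::setNames(O, levels(groups)),
                 expected = stats::setNames(E, levels(groups))),
            class = "survival_fit")
}

# Efron partial log-likelihood, gradient and Hessian at beta.
.cox_efron <- function(beta, times, events, X) {
  eta <- drop(X %*% beta)
  eta <- pmin(pmax(eta, -500), 500)
  w <- exp(eta)
  p <- ncol(X)
  ll <- 0; grad <- numeric(p); H <- matrix(0, p, p)
  for (tt in sort(unique(times[events == 1]))) {
    R <- which(times >= tt)
    D <- which(times == tt & events == 1)
    d <- length(D)
    sR <- sum(w[R]); sD <- sum(w[D])
    xR <- colSums(X[R, , drop = FALSE] * w[R])
    xD <- colSums(X[D, , drop = FALSE] * w[D])
    qR <- t(X[R, , drop = FALSE] * w[R]) %*% X[R, , drop = FALSE]
    qD <- t(X[D, , drop = FALSE] * w[D]) %*% X[D, , drop = FALSE]
    ll <- ll + sum(eta[D])
    for (l in seq_len(d) - 1L) {
      f <- l / d
      denom <- sR - f * sD
      xbar <- (xR - f * xD) / denom
      qbar <- (qR - f * qD) / denom
      ll <- ll - log(denom)
      grad <- grad - xbar
      H <- H - (qbar - outer(xbar, xbar))
    }
    grad <- grad + colSums(X[D, , drop = FALSE])
  }
  list(ll = ll, grad = grad, hessian = H)
}

#' Cox proportional-hazards fit (Efron tie handling)
#'
#' Newton-Raphson maximization of the Cox partial likelihood with the
#' Efron approximation for tied event times.  Reports, per covariate,
#' the hazard ratio `exp(beta)`, Wald 95% CI and two-sided Wald p.  For
#' a trend test across ordered groups, pass a single ordinal covariate
#' coded 0/1/2.
#'
#' @param times positive event/censoring times.
#' @param events 0/1 event indicators (>= 1 event required).
#' @param covariates data.frame or matrix of covariates; character/factor
#'   columns are expanded to treatment-coded indicators.
#' @param max_iter Newton iteration cap (default 50).
#' @param tol convergence tolerance on the coefficient step (default
#'   1e-9).
#' @return a `survival_fit` list with `model = "cox"`, `coefficients`
#'   data.frame (`term`, `beta`, `se`, `hr`, `ci_lower`, `ci_upper`,
#'   `p`), `loglik`, `n`, `n_event`, `iterations`.
#' @export
cox_fit <- function(times, events, covariates, max_iter = 50L, tol = 1e-9) {
  if (sum(events) < 1L) stop("no events")
  covariates <- as.data.frame(covariates)
  X <- stats::model.matrix(~ ., data = covariates)[, -1L, drop = FALSE]
  const <- apply(X, 2L, function(v) stats::sd(v) == 0)
  if (any(const))
    stop("constant covariate: ", paste(colnames(X)[const], collapse = ", "))
  p <- ncol(X)
  beta <- numeric(p)
  ll_prev <- -Inf
  for (it in seq_len(max_iter)) {
    e <- .cox_efron(beta, times, events, X)
    step <- tryCatch(solve(-e$hessian, e$grad), error = function(er) NULL)
    if (is.null(step))
      stop("singular information matrix in Cox fit")
    # step-halving if the likelihood would decrease
    half <- 0L
    repeat {
      cand <- beta + step
      ll_new <- .cox_efron(cand, times, events, X)$ll
      if (ll_new >= e$ll - 1e-12 || half >= 10L) break
      step <- step / 2
      half <- half + 1L
    }
    beta <- cand
    if (max(abs(step)) < tol) break
    if (it == max_iter)
      stop(sprintf("Cox fit did not converge in %d iterations (|grad| = %.3g)",
                   max_iter, sqrt(sum(e$grad^2))))
    ll_prev <- e$ll
  }
  e <- .cox_efron(beta, times, events, X)
  cov_b <- solve(-e$hessian)
  se <- sqrt(diag(cov_b))
  z <- beta / se
  cf <- data.frame(term = colnames(X), beta = beta, se = se,
                   hr = exp(beta),
                   ci_lower = exp(beta - 1.96 * se),
                   ci_upper = exp(beta + 1.96 * se),
                   p = 2 * stats::pnorm(-abs(z)),
                   stringsAsFactors = FALSE)
  rownames(cf) <- NULL
  structure(list(model = "cox", coefficients = cf, loglik = e$ll,
                 n = length(times), n_event = sum(events), iterations = it),
            class = "survival_fit")
}

#' @export
print.survival_fit <- function(x, ...) {
  cat(sprintf("<survival_fit> model = %s\n", x$model))
  if (x$model == "logrank")
    cat(sprintf("  chi-square = %.4g on %d df, p = %.3g\n",
                x$statistic, x$df, x$p))
  if (x$model == "cox") print(x$coefficients)
  invisible(x)
}
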