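make_pair_inputs <- function() {
  gen <- small_cohort()
  co <- gen$cohort
  sf <- size_factors(co$protein)
  rl <- rlog_like(co$protein, sf)
  tum <- co$clinical$sample_id[co$clinical$tissue == "tumor"]
  nor <- co$clinical$sample_id[co$clinical$tissue == "normal"]
  ps_t <- build_pair_set(co$protein, co$mrna, co$pairs, tum)
  list(gen = gen, co = co, rl = rl, tum = tum, nor = nor, ps = ps_t)
}

test_that("build_pair_set applies the group coverage rule", {
  set.seed(20)
  nn <- 38L
  m <- matrix(rpois(5 * nn, 10), 5, nn,
              dimnames = list(paste0("P", 1:5), sprintf("n%02d", 1:nn)))
  m[1, ] <- 0L; m[1, 1] <- 4L          # detected in 1 of 38 (< ceil(3.8)=4)
  m[2, ] <- 0L; m[2, 1:4] <- 2L        # detected in exactly 4 -> kept
  mr <- matrix(rnorm(4 * nn), 4, nn,
               dimnames = list(paste0("G", c(1, 2, 3, 5)), colnames(m)))
  pm <- pair_map(paste0("P", 1:5), paste0("G", 1:5))
  ps <- build_pair_set(omics_matrix(m, value_kind = "counts"),
                       omics_matrix(mr, value_kind = "log_intensity"),
                       pm, colnames(m))
  expect_false("P1" %in% ps$protein_id)   # coverage rule
  expect_true("P2" %in% ps$protein_id)
  expect_false("P4" %in% ps$protein_id)   # gene absent from mRNA
  expect_identical(ps$protein_id, sort(ps$protein_id))
  expect_error(build_pair_set(omics_matrix(m, value_kind = "counts"),
                              omics_matrix(mr, value_kind = "log_intensity"),
                              pair_map("P9", "G9"), colnames(m)),
               "empty pair set")
})

test_that("tumor and normal pair sets differ under group-dependent dropout", {
  x <- make_pair_inputs()
  ps_n <- build_pair_set(x$co$protein, x$co$mrna, x$co$pairs, x$nor)
  expect_false(nrow(x$ps) == nrow(ps_n) &&
                 identical(x$ps$protein_id, ps_n$protein_id))
})

test_that("within_sample_concordance equals a brute-force loop", {
  x <- make_pair_inputs()
  ws <- within_sample_concordance(x$rl, x$co$mrna, x$ps, x$tum)
  for (s in x$tum[c(1, 7, 15)]) {
    pv <- x$rl$values[x$ps$protein_id, s]
    mv <- x$co$mrna$values[x$ps$gene_id, s]
    expect_equal(ws$rho[ws$sample_id == s], as.numeric(spearman_rho(pv, mv)),
                 tolerance = 1e-12)
  }
  # monotone transform of one omic leaves scores unchanged
  rl2 <- x$rl
  rl2$values <- qnorm(pmin(pmax(
    (rl2$values - min(rl2$values)) /
      diff(range(rl2$values)), 1e-6), 1 - 1e-6))
  ws2 <- within_sample_concordance(rl2, x$co$mrna, x$ps, x$tum)
  expect_equal(ws2$rho, ws$rho, tolerance = 1e-12)
  # a sample that is a monotone transform scores rho 1
  mr3 <- x$co$mrna
  mr3$values[x$ps$gene_id, x$tum[1]] <- exp(x$rl$values[x$ps$protein_id,
                                                        x$tum[1]] / 4)
  ws3 <- within_sample_concordance(x$rl, mr3, x$ps, x$tum[1])
  expect_equal(ws3$rho, 1)
  # too few pairs -> NA with reason
  ps_small <- x$ps[1:10, ]
  class(ps_small) <- class(x$ps)
  ws4 <- within_sample_concordance(x$rl, x$co$mrna, ps_small, x$tum[1])
  expect_true(is.na(ws4$rho))
  expect_identical(ws4$reason, "insufficient_pairs")
})

test_that("per_pair_concordance matches the transposed oracle and orders stability", {
  x <- make_pair_inputs()
  pp <- per_pair_concordance(x$rl, x$co$mrna, x$ps, x$tum)
  for (i in c(2L, 40L)) {
    expect_equal(pp$rho[i],
                 as.numeric(spearman_rho(
                   x$rl$values[pp$protein_id[i], x$tum],
                   x$co$mrna$values[pp$gene_id[i], x$tum])),
                 tolerance = 1e-12)
  }
  st <- x$gen$truth$stability
  ss <- st$gene_id[st$protein_stable & st$mrna_stable]
  uu <- st$gene_id[!st$protein_stable & !st$mrna_stable]
  expect_gt(mean(pp$rho[pp$gene_id %in% ss], na.rm = TRUE),
            mean(pp$rho[pp$gene_id %in% uu], na.rm = TRUE))
  expect_error(per_pair_concordance(x$rl, x$co$mrna, x$ps, x$tum[1:5]),
               "at least 10")
})

test_that("compare_concordance picks the right test and p-values", {
  cmp <- compare_concordance(c(1, 2, 3, 4), c("a", "a", "b", "b"))
  expect_identical(cmp$test, "wilcoxon_rank_sum")
  expect_equal(cmp$p, 1 / 3, tolerance = 1e-12)
  cmp2 <- compare_concordance(c(1, 2, 3, 1, 2, 3), rep(c("a", "b"), each = 3))
  expect_gt(cmp2$p, 0.99)
  set.seed(21)
  sc <- rnorm(30)
  g3 <- rep(c("a", "b", "c"), 10)
  cmp3 <- compare_concordance(sc, g3)
  expect_identical(cmp3$test, "kruskal_wallis")
  expect_equal(cmp3$p, kruskal.test(sc, factor(g3))$p.value,
               tolerance = 1e-12)
  expect_error(compare_concordance(c(NA, NA, 1, 2),
                                   c("a", "a", "b", "b")), "only NA")
})

test_that("stratified_concordance reduces to the unstratified result", {
  x <- make_pair_inputs()
  full <- within_sample_concordance(x$rl, x$co$mrna, x$ps, x$tum)
  ex0 <- stratified_concordance(x$rl, x$co$mrna, x$ps, x$tum,
                                exclude = character(0))
  expect_equal(ex0$all$rho, full$rho)
  # abundance sextiles cover the pair set
  ab <- stratified_concordance(x$rl, x$co$mrna, x$ps, x$tum,
                               strata = "abundance", min_pairs = 10)
  expect_length(ab, 6L)
  expect_equal(sum(sapply(ab, function(r) attr(r, "n_pairs"))), nrow(x$ps))
  # excluding the (coupling-independent) ECM genes changes little
  ecm <- stratified_concordance(x$rl, x$co$mrna, x$ps, x$tum,
                                exclude = x$gen$truth$ecm_genes)
  expect_lt(abs(mean(ecm$all$rho, na.rm = TRUE) -
                  mean(full$rho, na.rm = TRUE)), 0.03)
})

test_that("subset_robustness is deterministic and concentrates near the full value", {
  x <- make_pair_inputs()
  grp <- rep("tumor", length(x$tum))
  r1 <- subset_robustness(x$rl, x$co$mrna, x$ps, x$tum, grp,
                          fraction = 0.5, n_reps = 20, seed = 9)
  r2 <- subset_robustness(x$rl, x$co$mrna, x$ps, x$tum, grp,
                          fraction = 0.5, n_reps = 20, seed = 9)
  expect_identical(r1$rep_means, r2$rep_means)
  # at ~150 pairs per subset the replicate means scatter around the
  # full-set value without bias (the +-0.02 concentration claim applies
  # at full cohort scale, not to this 300-gene fixture)
  expect_lt(abs(mean(r1$rep_means) - r1$full), 0.05)
  expect_lt(sd(r1$rep_means), 0.08)
  rf <- subset_robustness(x$rl, x$co$mrna, x$ps, x$tum, grp,
                          fraction = 1, n_reps = 3, seed = 1)
  expect_true(all(abs(rf$rep_means - rf$full) < 1e-12))
  expect_error(subset_robustness(x$rl, x$co$mrna, x$ps, x$tum, grp,
                                 fraction = 0.01), "too small")
})

test_that("adjusted_association computes partial correlations", {
  # hand case: covariate constant within pairs leaves proportional residuals
  res <- suppressWarnings(adjusted_association(c(1, 2, 3, 4), c(1, 2, 3, 4),
                                               data.frame(z = c(0, 0, 1, 1))))
  expect_equal(res$adjusted_correlation, 1, tolerance = 1e-12)
  # orthogonal covariate: adjusted equals unadjusted
  set.seed(22)
  x <- rnorm(100); y <- 0.5 * x + rnorm(100)
  z <- rnorm(100)
  z <- residuals(lm(z ~ x + y))  # force orthogonality
  r0 <- adjusted_association(y, x, NULL)
  r1 <- adjusted_association(y, x, data.frame(z = z))
  expect_equal(r1$adjusted_correlation, r0$adjusted_correlation,
               tolerance = 1e-10)
  expect_error(adjusted_association(y, x, data.frame(a = x, b = x)),
               "collinear")
})
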