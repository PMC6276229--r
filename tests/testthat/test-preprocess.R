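test_that("filter_features applies both rules in order and reconciles", {
  set.seed(10)
  n_s <- 20L
  m <- matrix(rpois(50 * n_s, 2), 50, n_s,
              dimnames = list(sprintf("P%02d", 1:50), sprintf("s%02d", 1:n_s)))
  m[1, ] <- 5L  # detected everywhere
  m[2, ] <- 0L; m[2, 1] <- 3L  # detected in 1 of 20 (< ceiling(2))
  om <- omics_matrix(m, value_kind = "counts")
  sup <- setNames(rep(5, 50), rownames(m))
  sup[c("P03", "P04")] <- 1
  res <- filter_features(om, peptide_support = sup)
  rep <- res$report
  expect_equal(rep$n_removed_peptide_rule, 2L)
  expect_true("P01" %in% rep$kept_ids)
  expect_false("P02" %in% rep$kept_ids)
  expect_false(any(c("P03", "P04") %in% rep$kept_ids))
  expect_equal(rep$n_input_features,
               length(rep$kept_ids) + rep$n_removed_peptide_rule +
                 rep$n_removed_coverage)
  # brute-force oracle: recompute both rules directly
  keep1 <- rownames(m)[sup[rownames(m)] >= 2]
  keep2 <- keep1[rowSums(m[keep1, ] > 0) >= ceiling(0.10 * n_s)]
  expect_identical(sort(rep$kept_ids), sort(keep2))
})

test_that("size_factors is the median-of-ratios with geometric mean 1", {
  m <- matrix(c(5L, 5L, 7L, 7L, 1L, 1L), 3, 2, byrow = TRUE,
              dimnames = list(c("a", "b", "c"), c("s1", "s2")))
  expect_equal(as.numeric(size_factors(omics_matrix(m, value_kind = "counts"))),
               c(1, 1))
  # hand case: geomeans 2.828, 8.485 -> ratios (0.7071, 1.4142)
  m2 <- matrix(c(2L, 4L, 6L, 12L), 2, 2, byrow = TRUE,
               dimnames = list(c("a", "b"), c("s1", "s2")))
  sf <- size_factors(omics_matrix(m2, value_kind = "counts"))
  expect_equal(as.numeric(sf), c(1 / sqrt(2), sqrt(2)), tolerance = 1e-12)
  # scaling one sample by 10 scales its factor by 10 (before rescale):
  # after geometric-mean-1 rescale the ratio of factors scales by 10
  m3 <- m2; m3[, 2] <- m3[, 2] * 10L
  sf3 <- size_factors(omics_matrix(m3, value_kind = "counts"))
  expect_equal(sf3[[2]] / sf3[[1]], 10 * sf[[2]] / sf[[1]], tolerance = 1e-12)
  # invariant under feature reordering
  set.seed(11)
  m4 <- matrix(rpois(200, 30) + 1L, 20, 10,
               dimnames = list(sprintf("f%02d", 1:20), sprintf("s%02d", 1:10)))
  o <- sample(20)
  expect_equal(as.numeric(size_factors(omics_matrix(m4, value_kind = "counts"))),
               as.numeric(size_factors(omics_matrix(m4[o, ],
                                                    value_kind = "counts"))))
  expect_error(size_factors(omics_matrix(
    matrix(c(0L, 1L, 1L, 0L), 2, 2,
           dimnames = list(c("a", "b"), c("x", "y"))),
    value_kind = "counts")), "positive")
})

test_that("rlog_like stabilizes variance and has the stated limits", {
  set.seed(12)
  m <- matrix(rpois(300, 8), 30, 10,
              dimnames = list(sprintf("f%02d", 1:30), sprintf("s%02d", 1:10)))
  m[1, ] <- 6L
  om <- omics_matrix(m, value_kind = "counts")
  sf <- setNames(rep(1, 10), colnames(m))
  y <- rlog_like(om, sf, prior_strength = 5)
  expect_identical(y$value_kind, "transformed")
  expect_equal(sd(y$values[1, ]), 0)  # constant normalized counts
  # prior -> 0 limit is the plain shifted log
  y0 <- rlog_like(om, sf, prior_strength = 1e-9)
  expect_equal(y0$values, log2(m + 0.5), tolerance = 1e-6,
               ignore_attr = TRUE)
  expect_error(rlog_like(om, sf, prior_strength = 0), "positive")

  # variance-mean decoupling: among low-mean genes the rank correlation of
  # per-gene SD with mean is no more negative than for the plain log
  set.seed(14)
  mu_true <- 2^runif(400, -1, 5.6)  # means 0.5 .. 50 counts
  mm <- matrix(rnbinom(400 * 24, mu = rep(mu_true, 24), size = 10), 400, 24,
               dimnames = list(sprintf("g%03d", 1:400), sprintf("s%02d", 1:24)))
  omm <- omics_matrix(mm, value_kind = "counts")
  sfm <- setNames(rep(1, 24), colnames(mm))
  rl <- rlog_like(omm, sfm)
  norm <- mm
  mu <- rowMeans(norm)
  low <- mu < 5 & mu > 0
  sd_rl <- apply(rl$values[low, ], 1, sd)
  sd_log <- apply(log2(norm + 0.5)[low, ], 1, sd)
  rho_rl <- suppressWarnings(cor(mu[low], sd_rl, method = "spearman"))
  rho_log <- suppressWarnings(cor(mu[low], sd_log, method = "spearman"))
  # plain log2 SD rises as the mean falls (negative correlation); the
  # shrinkage removes that inverse dependence
  expect_gte(rho_rl, rho_log)
  expect_gt(rho_rl, -0.1)
  expect_lt(rho_log, 0)
})

test_that("nb_wald controls type-I error and respects label symmetry", {
  set.seed(13)
  n <- 20L
  m <- matrix(rnbinom(800 * n, mu = 30, size = 10), 800, n,
              dimnames = list(sprintf("f%03d", 1:800), sprintf("s%02d", 1:n)))
  om <- omics_matrix(m, value_kind = "counts")
  grp <- rep(c("tumor", "normal"), each = n / 2)
  sf <- size_factors(om)
  de <- nb_wald(om, sf, grp)
  expect_true(all(de$p >= 0 & de$p <= 1, na.rm = TRUE))
  expect_true(all(de$q >= de$p - 1e-12, na.rm = TRUE))
  rej <- mean(de$p < 0.05, na.rm = TRUE)
  expect_gt(rej, 0.01); expect_lt(rej, 0.10)
  # a strong planted effect is detected
  m2 <- m
  m2[1, grp == "tumor"] <- rnbinom(n / 2, mu = 240, size = 10)
  de2 <- nb_wald(omics_matrix(m2, value_kind = "counts"), sf, grp)
  expect_lt(de2$q[1], 0.01)
  expect_identical(de2$direction[1], "up")
  expect_gt(de2$log2fc[1], 1.5)
  # all-zero feature excluded from testing
  m3 <- m; m3[2, ] <- 0L
  de3 <- nb_wald(omics_matrix(m3, value_kind = "counts"), sf, grp)
  expect_true(is.na(de3$p[2]) && is.na(de3$q[2]))
})

test_that("paired_signed_rank matches the primitive per feature", {
  gen <- small_cohort()
  rl <- rlog_like(gen$cohort$protein, size_factors(gen$cohort$protein))
  de <- paired_signed_rank(rl, gen$cohort$clinical)
  cl <- gen$cohort$clinical
  tum <- cl[cl$tissue == "tumor" & cl$pair_id != "", ]
  nor <- cl[cl$tissue == "normal", ]
  tid <- tum$sample_id[match(nor$pair_id, tum$pair_id)]
  for (i in c(1L, 50L, 200L)) {
    d <- rl$values[i, tid] - rl$values[i, nor$sample_id]
    expect_equal(de$p[i], signed_rank_test(d)$p)
    expect_equal(de$log2fc[i], median(d))
  }
  # fewer than 6 pairs errors
  cl_small <- cl[cl$sample_id %in% c(tid[1:3], nor$sample_id[1:3]), ]
  expect_error(paired_signed_rank(rl, cl_small), "6 complete")
})
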