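test_that("km_estimate reproduces the product-limit by hand and by oracle", {
  km <- km_estimate(c(1, 2, 3), c(1, 1, 0))
  cv <- km$curves[km$curves$time > 0, ]
  expect_equal(cv$survival, c(2 / 3, 1 / 3))  # censoring at 3 adds no row
  expect_equal(cv$n_risk, c(3L, 2L))
  # all censored: survival stays 1
  km2 <- km_estimate(c(1, 2, 3), c(0, 0, 0))
  expect_true(all(km2$curves$survival == 1))
  # doubling times rescales the time axis only
  km3 <- km_estimate(c(2, 4, 6), c(1, 1, 0))
  expect_equal(km3$curves$survival, km$curves$survival)
  expect_equal(km3$curves$time, km$curves$time * 2)
  # randomized comparison against the survival package
  for (seed in 1:10) {
    d <- random_surv(40, seed)
    mine <- km_estimate(d$times, d$events, d$groups)
    ref <- survival::survfit(survival::Surv(d$times, d$events) ~ d$groups)
    ref_sum <- summary(ref)
    for (g in c("a", "b")) {
      m_g <- mine$curves[mine$curves$group == g & mine$curves$n_event > 0, ]
      r_g <- ref_sum$surv[ref_sum$strata == paste0("d$groups=", g)]
      r_t <- ref_sum$time[ref_sum$strata == paste0("d$groups=", g)]
      expect_equal(m_g$survival, r_g, tolerance = 1e-10)
      expect_equal(m_g$time, r_t)
    }
  }
})

test_that("logrank_test matches hand computation and survdiff", {
  # identical groups: statistic 0
  lr0 <- logrank_test(c(1, 2, 3, 1, 2, 3), c(1, 1, 0, 1, 1, 0),
                      rep(c("a", "b"), each = 3))
  expect_lt(lr0$statistic, 1e-10)
  expect_gt(lr0$p, 0.99)
  # toy: A = {1,2} events, B = {3,4} events, walk the 4 risk sets by hand
  lr <- logrank_test(c(1, 2, 3, 4), c(1, 1, 1, 1), c("a", "a", "b", "b"))
  # O_a = 2; E_a = 2/4 + 1/3 = 5/6; V = 1/4 + 2/9 (last two risk sets add 0)
  expect_equal(unname(lr$observed["a"]), 2)
  expect_equal(unname(lr$expected["a"]), 2 / 4 + 1 / 3, tolerance = 1e-12)
  expect_equal(lr$statistic, (2 - 5 / 6)^2 / (1 / 4 + 2 / 9),
               tolerance = 1e-12)
  for (seed in 11:25) {
    d <- random_surv(50, seed)
    if (sum(d$events) == 0) next
    mine <- logrank_test(d$times, d$events, d$groups)
    ref <- survival::survdiff(survival::Surv(d$times, d$events) ~ d$groups)
    expect_equal(mine$statistic, unname(ref$chisq), tolerance = 1e-8)
  }
})

test_that("cox_fit agrees with coxph under Efron ties", {
  for (seed in 31:40) {
    set.seed(seed)
    n <- 60
    x <- rnorm(n)
    g <- rbinom(n, 1, 0.5)
    t_ <- round(rexp(n, exp(0.5 * x + 0.7 * g) * 0.1), 1) + 0.1  # ties likely
    e_ <- rbinom(n, 1, 0.8)
    if (sum(e_) < 5) next
    mine <- cox_fit(t_, e_, data.frame(x = x, g = g))
    ref <- survival::coxph(survival::Surv(t_, e_) ~ x + g, ties = "efron")
    expect_equal(mine$coefficients$beta, unname(coef(ref)), tolerance = 1e-6)
    expect_equal(mine$coefficients$se,
                 unname(sqrt(diag(vcov(ref)))), tolerance = 1e-6)
  }
  expect_error(cox_fit(c(1, 2, 3), c(1, 1, 0), data.frame(x = c(1, 1, 1))),
               "constant")
  expect_error(cox_fit(c(1, 2, 3), c(0, 0, 0), data.frame(x = 1:3)),
               "no events")
})

test_that("log-rank equals the Cox score test direction on tie-free data", {
  set.seed(41)
  n <- 80
  g <- rbinom(n, 1, 0.5)
  t_ <- rexp(n, exp(0.8 * g) * 0.05) + runif(n, 0, 1e-4)  # no ties
  e_ <- rbinom(n, 1, 0.9)
  lr <- logrank_test(t_, e_, g)
  cx <- cox_fit(t_, e_, data.frame(g = g))
  # the two chi-square-scale statistics agree asymptotically
  expect_equal(sign(cx$coefficients$beta), 1)
  expect_lt(abs(sqrt(lr$statistic) -
                  abs(cx$coefficients$beta / cx$coefficients$se)), 0.5)
})

test_that("concordance_groups cuts at interpolated quartiles with ties to mid", {
  s <- setNames(1:8, paste0("t", 1:8))
  g <- concordance_groups(s)
  expect_equal(as.vector(table(g)), c(2, 4, 2))
  expect_identical(unname(g[1]), factor("low", c("low", "mid", "high"))[1])
  # a score tied with the boundary goes to mid: for 1..9 the lower
  # quartile is exactly 3 (type-7 interpolation), so t3 is mid, not low
  s2 <- setNames(1:9, paste0("t", 1:9))
  expect_equal(unname(quantile(s2, 0.25)), 3)
  g2 <- concordance_groups(s2)
  expect_identical(as.character(g2["t3"]), "mid")
  expect_identical(as.character(g2["t2"]), "low")
  expect_error(concordance_groups(setNames(rep(1, 10), paste0("t", 1:10))),
               "identical")
  expect_error(concordance_groups(setNames(1:5, paste0("t", 1:5))), "8")
})

test_that("proliferation_score sums (standardized) marker genes", {
  expect_length(proliferation_gene_list, 11L)
  expect_true(all(c("BIRC5", "MKI67", "UBE2C") %in% proliferation_gene_list))
  m <- matrix(0, 11, 4, dimnames = list(proliferation_gene_list,
                                        paste0("s", 1:4)))
  om <- omics_matrix(m, value_kind = "log_intensity")
  sc <- proliferation_score(om, standardize = FALSE)
  expect_equal(unname(sc$score), rep(0, 4))
  # missing genes are reported, not fatal
  om2 <- omics_matrix(m[1:5, , drop = FALSE], value_kind = "log_intensity")
  sc2 <- proliferation_score(om2)
  expect_length(sc2$genes_missing, 6L)
  expect_error(proliferation_score(
    omics_matrix(matrix(0, 1, 2, dimnames = list("XX", c("a", "b"))),
                 value_kind = "log_intensity")), "none of")
  # standardization makes the score scale-free per gene
  set.seed(42)
  m3 <- matrix(rnorm(44), 11, 4, dimnames = dimnames(m))
  m4 <- m3 * 7 + 3
  s3 <- proliferation_score(omics_matrix(m3, value_kind = "log_intensity"))
  s4 <- proliferation_score(omics_matrix(m4, value_kind = "log_intensity"))
  expect_equal(s3$score, s4$score, tolerance = 1e-12)
})

test_that("the planted proliferation signal correlates with concordance", {
  gen <- small_cohort()
  co <- gen$cohort
  sc <- proliferation_score(co$mrna, gene_list = gen$truth$prolif_genes)
  tum <- co$clinical$sample_id[co$clinical$tissue == "tumor"]
  r <- cor(sc$score[tum], gen$truth$prolif_level[tum])
  expect_gt(r, 0.8)
})
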