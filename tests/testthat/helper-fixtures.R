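# Shared fixtures: one small synthetic cohort reused across test files
# (generated once per test run), plus tiny hand-built matrices.

.fixture_env <- new.env(parent = emptyenv())

small_cohort <- function() {
  if (is.null(.fixture_env$small)) {
    cfg <- sim_config(n_genes = 300, n_tumors = 16, n_normals = 12,
                      n_pathways = 12, pathway_size = 15,
                      n_planted_pathways = 3,
                      calibration_passes = 1L, calibration_iters = 14L,
                      fold_calibrate = FALSE, seed = 42L)
    .fixture_env$small <- c(generate_cohort(cfg), list(cfg = cfg))
  }
  .fixture_env$small
}

# a tiny deterministic count matrix
toy_counts <- function() {
  m <- matrix(c(2L, 4L, 6L, 12L, 0L, 3L), nrow = 3, byrow = TRUE,
              dimnames = list(c("P1", "P2", "P3"), c("s1", "s2")))
  omics_matrix(m, value_kind = "counts")
}

# random small survival data
random_surv <- function(n, seed) {
  set.seed(seed)
  list(times = round(rexp(n, 0.1) + 0.1, 1),
       events = rbinom(n, 1, 0.7),
       groups = sample(c("a", "b"), n, replace = TRUE))
}
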