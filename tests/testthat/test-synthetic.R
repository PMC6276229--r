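test_that("sim_config validates its inputs", {
  expect_error(sim_config(n_genes = 50), "n_genes")
  expect_error(sim_config(n_tumors = 3), "n_tumors")
  expect_error(sim_config(coupling_tumor_mean = 0.99), "infeasible")
  expect_error(sim_config(de_fraction_up = 1.2), "de_fraction_up")
  expect_error(sim_config(de_fraction_up = 0.6, de_fraction_down = 0.4),
               "sum")
  expect_error(sim_config(pathway_size = 5000), "pathway_size")
  expect_error(sim_config(nb_dispersion = 0), "nb_dispersion")
})

test_that("generate_cohort is deterministic given the config", {
  cfg <- sim_config(n_genes = 150, n_tumors = 8, n_normals = 6,
                    calibration_passes = 1L, calibration_iters = 12L,
                    fold_calibrate = FALSE, seed = 5L)
  g1 <- generate_cohort(cfg)
  g2 <- generate_cohort(cfg)
  expect_identical(g1$cohort$protein$values, g2$cohort$protein$values)
  expect_identical(g1$cohort$mrna$values, g2$cohort$mrna$values)
  expect_identical(g1$truth$de_up, g2$truth$de_up)
  cfg3 <- sim_config(n_genes = 150, n_tumors = 8, n_normals = 6,
                     calibration_passes = 1L, calibration_iters = 12L,
                     fold_calibrate = FALSE, seed = 6L)
  g3 <- generate_cohort(cfg3)
  expect_false(identical(g1$cohort$protein$values, g3$cohort$protein$values))
})

test_that("the cohort satisfies its structural invariants", {
  gen <- small_cohort()
  co <- gen$cohort; tr <- gen$truth
  expect_identical(co$protein$value_kind, "counts")
  expect_true(all(co$protein$values >= 0))
  expect_s3_class(co$clinical, "sample_table")
  # every truth id resolves in the cohort
  for (ids in list(tr$de_up, tr$de_down, tr$utr_genes, tr$ecm_genes,
                   tr$block_genes, tr$prolif_genes))
    expect_true(all(ids %in% co$mrna$feature_ids))
  expect_true(all(names(tr$nmf_group) %in% co$clinical$sample_id))
  # survival present exactly for tumors
  tum <- co$clinical$tissue == "tumor"
  expect_true(all(!is.na(co$clinical$surv_time[tum])))
  expect_true(all(is.na(co$clinical$surv_time[!tum])))
  expect_true(all(co$clinical$surv_time[tum] > 0))
  # hazard group is the coupling tertile
  expect_equal(unname(tr$hazard_group[order(tr$coupling[tum])]),
               unname(sort(tr$hazard_group)))
})

test_that("detection dropout is monotone in latent abundance", {
  gen <- small_cohort()
  a <- gen$truth$internals$a_g
  det <- rowMeans(gen$cohort$protein$values > 0)
  bins <- cut(a, quantile(a, seq(0, 1, 0.125)), include.lowest = TRUE)
  freq <- tapply(det, bins, mean)
  expect_true(all(diff(freq) > -0.02))
  expect_gt(freq[length(freq)], freq[1])
})

test_that("protein DE direction is realized for truth up-genes", {
  gen <- small_cohort()
  co <- gen$cohort; tr <- gen$truth
  cl <- co$clinical
  tum <- cl[cl$tissue == "tumor" & cl$pair_id != "", ]
  nor <- cl[cl$tissue == "normal", ]
  tid <- tum$sample_id[match(nor$pair_id, tum$pair_id)]
  sf <- size_factors(co$protein)
  lg <- log2(sweep(co$protein$values, 2, as.numeric(sf), "/") + 0.5)
  d <- lg[, tid] - lg[, nor$sample_id]
  med <- apply(d, 1, median)
  pid_up <- co$pairs$protein_id[match(tr$de_up, co$pairs$gene_id)]
  expect_gt(mean(med[pid_up] > 0), 0.90)
})

test_that("generated gene sets are deterministic and planted from stable genes", {
  gen <- small_cohort()
  sets1 <- generate_gene_sets(gen$cfg, gen$truth)
  sets2 <- generate_gene_sets(gen$cfg, gen$truth)
  expect_identical(sets1$sets, sets2$sets)
  expect_length(sets1$sets, gen$cfg$n_pathways)
  expect_true(all(lengths(sets1$sets) == gen$cfg$pathway_size))
  stable <- gen$truth$stability
  pool <- stable$gene_id[stable$protein_stable & stable$mrna_stable]
  for (nm in gen$truth$planted_pathways)
    expect_true(all(sets1$sets[[nm]] %in% pool))
})

test_that("write_cohort emits a complete, re-readable directory", {
  gen <- small_cohort()
  d <- withr::local_tempdir()
  sets <- generate_gene_sets(gen$cfg, gen$truth)
  write_cohort(gen$cohort, gen$truth, sets, d)
  prot <- read_matrix(file.path(d, "protein_counts.tsv"), "counts")
  expect_equal(prot$values, gen$cohort$protein$values, ignore_attr = TRUE)
  mr <- read_matrix(file.path(d, "mrna_log2.tsv"), "log_intensity")
  expect_equal(mr$values, gen$cohort$mrna$values, tolerance = 1e-9,
               ignore_attr = TRUE)
  expect_identical(read_gene_sets(file.path(d, "sets.gmt"))$sets, sets$sets)
  expect_identical(read_id_list(file.path(d, "annotations/utr_genes.txt")),
                   gen$truth$utr_genes)
  tr <- jsonlite::read_json(file.path(d, "truth.json"), simplifyVector = TRUE)
  expect_equal(sort(tr$de_up), sort(gen$truth$de_up))
})
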