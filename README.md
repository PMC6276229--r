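# proteoconcord

Integrated protein–mRNA concordance analysis for paired tumor /
adjacent-normal cohorts.

## The problem

Label-free shotgun proteomics quantifies proteins as spectral counts
(peptide–spectrum matches per protein per sample); expression arrays
quantify the matched transcriptome as log2 intensities.  The proteome
and transcriptome of a tumor describe partially different biology, and
the degree to which they agree is itself a per-sample phenotype.  This
package implements that analysis end to end for users with a protein
count matrix, an mRNA log2-intensity matrix, a protein↔gene mapping and
a clinical table:

* **Preprocessing** — peptide-support and detection-coverage filtering,
  median-of-ratios size factors, a regularized (variance-stabilized)
  log transform, negative-binomial Wald and paired signed-rank
  differential abundance with Benjamini–Hochberg FDR.
* **Concordance** — the core statistic.  Within-sample concordance of
  sample *s* is the tie-corrected Spearman correlation
  ρ<sub>s</sub> = cor(midrank(p<sub>·s</sub>), midrank(m<sub>·s</sub>))
  across protein–mRNA pairs; across-subject concordance is the per-pair
  Spearman across samples.  Group comparisons (rank-sum /
  Kruskal–Wallis), abundance/coverage/annotation stratifications,
  random-subset robustness, covariate-adjusted (partial) correlations.
* **Enrichment** — GSEA-style weighted-KS pre-ranked scores with
  permutation NES/FDR, and two-sample KS enrichment of gene sets in
  per-pair concordance.
* **Survival** — 11-gene cell-cycle proliferation metagene
  (BIRC5, CCNB1, CDC20, CEP55, MKI67, NDC80, NUF2, PTTG1, RRM2, TYMS,
  UBE2C), quartile concordance groups, Kaplan–Meier, log-rank, and a
  from-scratch Cox partial-likelihood fit with Efron tie handling
  (hazard ratios, Wald CIs, ordinal trend tests, covariate adjustment),
  plus Fisher's exact composition tests.
* **Subtyping** — consensus non-negative matrix factorization
  (generalized-KL multiplicative updates, seeded restarts, cophenetic
  rank selection) of the most variable proteins.
* **3′UTR contrast** — paired fold-change comparison of a flagged gene
  set (e.g. genes with tumor-associated 3′UTR shortening, which raises
  protein output without raising mRNA) against the background.
* **Synthetic cohorts** — a first-class generator that emulates the
  statistical structure all of the above assumes, with per-sample
  coupling calibrated on the rank scale and a ground-truth record for
  recovery tests.  See the methods vignette
  (`vignettes/proteoconcord-methods.Rmd`) for the model and every
  numerical convention.

## Worked example

```r
library(proteoconcord)

cfg <- sim_config(n_genes = 500, n_tumors = 20, n_normals = 15,
                  calibration_passes = 1, seed = 1)
gen <- generate_cohort(cfg)
co  <- gen$cohort

flt <- filter_features(co$protein)
print(flt$report)
#> <filter_report> 500 features in; 0 removed by peptide rule, 2 by coverage (< 4 samples); 498 kept

sf <- size_factors(flt$matrix)
rl <- rlog_like(flt$matrix, sf)
rhos <- list()
for (g in c("tumor", "normal")) {
  sm <- co$clinical$sample_id[co$clinical$tissue == g]
  ps <- build_pair_set(co$protein, co$mrna, co$pairs, sm)
  ws <- within_sample_concordance(rl, co$mrna, ps, sm)
  rhos[[g]] <- ws$rho
  cat(sprintf("%s: %d pairs, mean within-sample rho = %.3f\n",
              g, nrow(ps), mean(ws$rho, na.rm = TRUE)))
}
#> tumor: 497 pairs, mean within-sample rho = 0.322
#> normal: 498 pairs, mean within-sample rho = 0.201

compare_concordance(c(rhos$tumor, rhos$normal),
                    rep(c("tumor", "normal"), c(20, 15)))
#> <group_comparison> wilcoxon_rank_sum: statistic = 6, p = 1.59e-06

foldchange_contrast(rl, co$mrna, co$pairs, co$clinical, gen$truth$utr_genes)
#> <foldchange_contrast> 25 set / 473 background genes, 15 pairs
#>   protein: set 1.75-fold vs background 1.40-fold (rank-sum p = 0.00493)
#>   mRNA:    set 1.06-fold vs background 1.00-fold (rank-sum p = 0.372)
```

Reading: tumors track their transcriptome more closely than adjacent
normal tissue (mean ρ 0.32 vs 0.20, rank-sum p ≈ 2 × 10⁻⁶ — the
generator's design values are 0.31 / 0.19), and the 3′UTR-flagged set
is up 1.75-fold at the protein level against a 1.40-fold background
with no matching transcript change — exactly the planted protein-only
effect.

## Command line

```sh
Rscript -e 'proteoconcord::run_cli()' simulate   --config cfg.yaml --out run/
Rscript -e 'proteoconcord::run_cli()' preprocess --config cfg.yaml --out run/
Rscript -e 'proteoconcord::run_cli()' all        --config cfg.yaml --out run/
```

(or use the installed wrapper at
`system.file("cli", "proteoconcord", package = "proteoconcord")`).
Subcommands: `simulate`, `preprocess`, `concordance`, `enrich`,
`survival`, `nmf`, `utr`, `all`.  Config is YAML or JSON mirroring the
function arguments; every run writes `run_log.json` with the resolved
config and seed.  Formats: TSV matrices, CSV clinical tables, GMT gene
sets, one-id-per-line annotation lists, JSON results.

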