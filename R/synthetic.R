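#' Simulation configuration for a paired proteotranscriptomic cohort
#'
#' Defaults describe the cohort shape and effect sizes the analysis is
#' designed around: 2000 genes, 59 tumors and 38 paired adjacent-normal
#' tissues; mean within-sample protein-mRNA Spearman coupling 0.31 in
#' tumors and 0.19 in normals, graded across subtypes; a right-skewed
#' tumor protein fold-change distribution with mean background fold 1.41
#' and a 3'UTR-shortened gene subset with protein-only mean fold 1.77;
#' NB-distributed spectral counts with logistic abundance-dependent
#' detection dropout; exponential survival whose log hazard increases by
#' `hazard_log_hr_per_group` per coupling tertile; planted
#' concordance-enriched pathways; and a two-block protein structure
#' aligned with a Myc-signature label.
#'
#' @param n_genes number of genes (>= 100); each has one protein.
#' @param n_tumors,n_normals cohort sizes; the first `n_normals` tumors
#'   are paired with a normal.
#' @param coupling_tumor_mean,coupling_normal_mean target mean
#'   within-sample Spearman rho per tissue group.
#' @param coupling_sd per-sample spread of true coupling targets.
#' @param coupling_by_subtype named offsets added to tumor targets by
#'   subtype (targets are re-centered so the tumor mean is preserved).
#' @param de_fraction_up,de_fraction_down fractions of genes in the up /
#'   down components of the tumor protein fold-change mixture.
#' @param de_lfc_down_mean,de_lfc_up_sd,de_lfc_down_sd,de_null_sd mixture
#'   shape parameters (log2); the up-component mean is solved so the mean
#'   background log2 fold equals `log2(background_protein_fc)`.
#' @param background_protein_fc mean tumor/normal protein fold change of
#'   non-3'UTR genes (the geometric-mean summary target).
#' @param utr_fraction fraction of genes flagged 3'UTR-shortened.
#' @param utr_protein_fc mean protein-only tumor fold change of flagged
#'   genes (their mRNA fold is ~1).
#' @param utr_lfc_sd per-gene spread (log2) around `log2(utr_protein_fc)`.
#' @param mrna_de_fraction fraction of genes with an mRNA tumor shift in
#'   each direction (symmetric by design: transcript changes are balanced
#'   while protein changes are up-skewed).
#' @param mrna_de_lfc magnitude (log2) of the mRNA tumor shift.
#' @param detection_midpoint,detection_slope logistic dropout:
#'   P(observed) = plogis(slope * (latent_log2_abundance - midpoint)).
#' @param nb_dispersion NB dispersion of spectral counts (1/size).
#' @param lib_sd sdlog of the log-normal per-sample library size.
#' @param hazard_base baseline event rate (events/month).
#' @param hazard_log_hr_per_group log hazard-ratio step per coupling
#'   tertile (low -> mid -> high).
#' @param nmf_hazard_hr extra hazard ratio for planted NMF group 1 tumors
#'   (1 = no effect).
#' @param censor_min,censor_max uniform censoring window (months).
#' @param n_pathways,pathway_size,n_planted_pathways gene-set layout;
#'   planted sets are drawn from stable-stable (high across-subject
#'   concordance) genes.
#' @param planted_block_fraction fraction of tumors in NMF group 1.
#' @param block_gene_fraction,block_lfc size and strength (log2) of the
#'   protein block signal carried by group 1 tumors.
#' @param myc_concordance probability that a group 1 tumor carries the
#'   Myc-signature flag (group 2: 1 - this).
#' @param prolif_n_genes,prolif_cor,prolif_effect proliferation metagene:
#'   number of marker genes, correlation of the per-tumor proliferation
#'   level with true coupling, and its mRNA effect size (log2 per SD).
#' @param ecm_fraction fraction of genes labeled extracellular-matrix
#'   (coupling-independent by design).
#' @param mrna_baseline_mean,mrna_baseline_sd,bio_sd log2 mRNA baseline
#'   distribution and shared biological variation propagated to protein.
#' @param mrna_noise_stable,mrna_noise_unstable,protein_noise_stable,protein_noise_unstable
#'   per-gene noise SDs for the stability classes (each gene is stable
#'   with probability 1/2 per omic).
#' @param protein_baseline_mean,protein_baseline_sd log2 protein latent
#'   abundance baseline.
#' @param calibration_passes 2 (default) recalibrates coupling on the
#'   coverage-filtered gene set; 1 is faster for small replicate studies.
#' @param calibration_iters bisection iterations per sample for the
#'   coupling calibration (default 18; 14 is enough for replicate
#'   studies at reduced size).
#' @param fold_calibrate calibrate the latent fold components so that the
#'   measured (post size-factor normalization and rlog) mean background
#'   and 3'UTR-set folds hit `background_protein_fc` / `utr_protein_fc`
#'   (default TRUE; requires >= 6 pairs and >= 10 flagged genes).
#' @param seed integer RNG seed.
#' @return a validated `sim_config` list.
#' @export
sim_config <- function(n_genes = 2000, n_tumors = 59, n_normals = 38,
                       coupling_tumor_mean = 0.31,
                       coupling_normal_mean = 0.19,
                       coupling_sd = 0.04,
                       coupling_by_subtype = c(luminalA = -0.04, HER2 = 0,
                                               TN_basal = 0.06, other = 0),
                       de_fraction_up = 0.30, de_fraction_down = 0.20,
                       de_lfc_down_mean = -0.7, de_lfc_up_sd = 0.6,
                       de_lfc_down_sd = 0.3, de_null_sd = 0.08,
                       background_protein_fc = 1.41,
                       utr_fraction = 0.05, utr_protein_fc = 1.77,
                       utr_lfc_sd = 0.2,
                       mrna_de_fraction = 0.15, mrna_de_lfc = 1.0,
                       detection_midpoint = 4.5, detection_slope = 4,
                       nb_dispersion = 0.05, lib_sd = 0.3,
                       hazard_base = 0.02,
                       hazard_log_hr_per_group = log(2),
                       nmf_hazard_hr = 1,
                       censor_min = 12, censor_max = 150,
                       n_pathways = 50, pathway_size = 40,
                       n_planted_pathways = 5,
                       planted_block_fraction = 0.35,
                       block_gene_fraction = 0.15, block_lfc = 2.5,
                       myc_concordance = 0.9,
                       prolif_n_genes = 11, prolif_cor = 0.7,
                       prolif_effect = 1.0,
                       ecm_fraction = 0.075,
                       mrna_baseline_mean = 7, mrna_baseline_sd = 1.5,
                       bio_sd = 0.6,
                       mrna_noise_stable = 0.15, mrna_noise_unstable = 0.7,
                       protein_noise_stable = 0.25,
                       protein_noise_unstable = 0.8,
                       protein_baseline_mean = 8, protein_baseline_sd = 1.5,
                       calibration_passes = 2L,
                       calibration_iters = 18L,
                       fold_calibrate = TRUE,
                       seed = 1L) {
  cfg <- as.list(environment())
  fr <- c(de_fraction_up = de_fraction_up, de_fraction_down = de_fraction_down,
          utr_fraction = utr_fraction, mrna_de_fraction = mrna_de_fraction,
          planted_block_fraction = planted_block_fraction,
          block_gene_fraction = block_gene_fraction,
          ecm_fraction = ecm_fraction)
  bad <- fr < 0 | fr > 1
  if (any(bad)) stop(names(fr)[bad][1L], " must be in [0,1]")
  if (de_fraction_up + de_fraction_down + utr_fraction >= 1)
    stop("DE and 3'UTR fractions sum to >= 1")
  if (n_genes < 100) stop("n_genes must be >= 100")
  if (n_tumors < 4) stop("n_tumors must be >= 4")
  if (abs(coupling_tumor_mean) > 0.98 || abs(coupling_normal_mean) > 0.98)
    stop("infeasible coupling target (|rho| > 0.98)")
  if (nb_dispersion <= 0) stop("nb_dispersion must be positive")
  if (hazard_base <= 0) stop("hazard_base must be positive")
  if (pathway_size > n_genes) stop("pathway_size exceeds n_genes")
  cfg$seed <- as.integer(seed)
  class(cfg) <- "sim_config"
  cfg
}

# Realized within-sample Spearman for one sample at coupling scale cc,
# using fixed random draws (so the map cc -> rho is deterministic and
# increasing).
.sample_rho <- function(cc, base_latent, z, noise, u, v, lib, mrna_obs,
                        cfg, idx) {
  latent <- pmin(base_latent + cc * z + noise, 26)
  mu <- 2^latent * lib
  counts <- stats::qnbinom(u, size = 1 / cfg$nb_dispersion, mu = mu)
  detp <- stats::plogis(cfg$detection_slope * (latent - cfg$detection_midpoint))
  counts[v >= detp] <- 0L
  spearman_rho(counts[idx], mrna_obs[idx])
}

.calibrate_c <- function(target, base_latent, z, noise, u, v, lib, mrna_obs,
                         cfg, idx, n_iter = cfg$calibration_iters %||% 18L) {
  lo <- -25; hi <- 25
  for (i in seq_len(n_iter)) {
    mid <- (lo + hi) / 2
    r <- .sample_rho(mid, base_latent, z, noise, u, v, lib, mrna_obs, cfg,
                     idx)
    if (is.na(r)) r <- 0
    if (r < target) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

#' Generate a paired tumor/normal proteome + transcriptome cohort
#'
#' Simulates the data model the concordance analysis assumes.  mRNA log2
#' intensities are Gaussian per gene around a baseline, with symmetric
#' tumor shifts for mRNA-DE genes, a shared biological component, and
#' per-gene measurement noise.  The protein latent log2 abundance is
#' `a_g + delta_g*tumor + block + c_s * z_s(mRNA_bio) + noise`, where
#' `z_s` standardizes the biological mRNA signal across genes within a
#' sample and `c_s` is calibrated per sample, by bisection against the
#' sample's own fixed random draws, so that the realized within-sample
#' Spearman rho (on spectral counts after dropout) matches the sample's
#' true coupling.  Spectral counts are negative binomial around
#' `2^latent * lib_s` and are zeroed with probability
#' `1 - plogis(slope*(latent - midpoint))` (detection dropout).  Tumor
#' protein fold changes are drawn from a right-skewed median-zero
#' mixture; because median-of-ratios normalization anchors each sample
#' near the smoothed median of its fold distribution, the up-component
#' and flagged-3'UTR shifts are then calibrated (a damped Gauss-Seidel
#' loop that re-runs the coupling calibration on every evaluation) so
#' the *measured* mean background and set folds, after size-factor
#' normalization and the rlog-style transform, equal
#' `background_protein_fc` and `utr_protein_fc`; the flagged genes'
#' mRNA fold stays ~1 (protein-only effect).
#' Survival is exponential with log hazard increasing per coupling
#' tertile; NMF group 1 tumors carry an additive protein block signal and
#' (with probability `myc_concordance`) a Myc-signature flag.
#'
#' Deterministic given the config (the seed is part of it).
#'
#' @param cfg a [sim_config()].
#' @return list with `cohort` (a `paired_cohort`: `protein` counts
#'   `omics_matrix`, `mrna` log-intensity `omics_matrix`, `clinical`
#'   `sample_table`, `pairs` `pair_map`) and `truth` (a `synthetic_truth`
#'   list with per-sample coupling, DE/3'UTR/ECM/block/proliferation gene
#'   ids, stability labels, planted pathway names, NMF groups, Myc flags
#'   and hazard groups).
#' @export
generate_cohort <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  ng <- cfg$n_genes
  nt <- cfg$n_tumors
  nn <- cfg$n_normals
  if (nn > nt) stop("n_normals may not exceed n_tumors (pairing)")
  genes <- sprintf("GENE%04d", seq_len(ng))
  prots <- sprintf("P%05d", seq_len(ng))
  tum_ids <- sprintf("T%03d", seq_len(nt))
  nor_ids <- sprintf("N%03d", seq_len(nn))
  samples <- c(tum_ids, nor_ids)
  ns <- nt + nn
  is_tumor <- c(rep(TRUE, nt), rep(FALSE, nn))

  ## ---- gene roles -------------------------------------------------------
  pool <- seq_len(ng)
  utr_idx <- sort(sample(pool, round(cfg$utr_fraction * ng)))
  rest <- setdiff(pool, utr_idx)
  n_up <- round(cfg$de_fraction_up * ng)
  n_dn <- round(cfg$de_fraction_down * ng)
  de_pick <- sample(rest, n_up + n_dn)
  up_idx <- sort(de_pick[seq_len(n_up)])
  dn_idx <- sort(de_pick[n_up + seq_len(n_dn)])
  block_idx <- sort(sample(setdiff(pool, utr_idx),
                           max(2L, round(cfg$block_gene_fraction * ng))))
  prolif_idx <- sort(sample(setdiff(pool, c(utr_idx, block_idx)),
                            cfg$prolif_n_genes))
  ecm_idx <- sort(sample(pool, round(cfg$ecm_fraction * ng)))
  m_up_idx <- sort(sample(rest, round(cfg$mrna_de_fraction * ng)))
  m_dn_idx <- sort(sample(setdiff(rest, m_up_idx),
                          round(cfg$mrna_de_fraction * ng)))

  ## ---- gene-level parameters -------------------------------------------
  mu_g <- stats::rnorm(ng, cfg$mrna_baseline_mean, cfg$mrna_baseline_sd)
  a_g <- stats::rnorm(ng, cfg$protein_baseline_mean, cfg$protein_baseline_sd)
  mrna_stable <- stats::runif(ng) < 0.5
  prot_stable <- stats::runif(ng) < 0.5
  tau_g <- ifelse(mrna_stable, cfg$mrna_noise_stable, cfg$mrna_noise_unstable)
  sig_g <- ifelse(prot_stable, cfg$protein_noise_stable,
                  cfg$protein_noise_unstable)

  ## ---- tumor protein fold-change mixture -------------------------------
  # up-component mean solved so the background mean log2 fold hits target
  f_up <- cfg$de_fraction_up; f_dn <- cfg$de_fraction_down
  target_bg <- log2(cfg$background_protein_fc)
  m_up <- if (f_up > 0)
    (target_bg - f_dn * cfg$de_lfc_down_mean) / f_up else 0
  delta <- stats::rnorm(ng, 0, cfg$de_null_sd)
  delta[up_idx] <- stats::rnorm(n_up, m_up, cfg$de_lfc_up_sd)
  delta[dn_idx] <- stats::rnorm(n_dn, cfg$de_lfc_down_mean, cfg$de_lfc_down_sd)
  delta[utr_idx] <- stats::rnorm(length(utr_idx), log2(cfg$utr_protein_fc),
                                 cfg$utr_lfc_sd)
  dm <- numeric(ng)
  dm[m_up_idx] <- cfg$mrna_de_lfc
  dm[m_dn_idx] <- -cfg$mrna_de_lfc

  ## ---- clinical covariates ---------------------------------------------
  subtype <- sample(c("luminalA", "HER2", "TN_basal", "other"), nt,
                    replace = TRUE, prob = c(0.40, 0.15, 0.25, 0.20))
  grade <- sample(1:3, nt, replace = TRUE, prob = c(0.2, 0.5, 0.3))
  er <- ifelse(subtype == "TN_basal",
               ifelse(stats::runif(nt) < 0.9, "neg", "pos"),
               ifelse(stats::runif(nt) < 0.8, "pos", "neg"))
  race <- sample(c("AA", "EA"), nt, replace = TRUE, prob = c(0.45, 0.55))

  ## ---- coupling targets -------------------------------------------------
  # subtype offsets are centered (so they grade coupling without moving
  # the group mean); the per-sample noise is left uncentered so that
  # group means carry honest sampling variability
  off <- cfg$coupling_by_subtype[subtype]
  off[is.na(off)] <- 0
  rho_t <- cfg$coupling_tumor_mean + (off - mean(off)) +
    stats::rnorm(nt, 0, cfg$coupling_sd)
  rho_n <- cfg$coupling_normal_mean + stats::rnorm(nn, 0, cfg$coupling_sd)
  rho_true <- pmin(pmax(c(rho_t, rho_n), -0.97), 0.97)
  names(rho_true) <- samples

  ## ---- planted NMF groups, Myc flags, proliferation --------------------
  n_g1 <- max(1L, round(cfg$planted_block_fraction * nt))
  g1 <- sample(seq_len(nt), n_g1)
  nmf_group <- ifelse(seq_len(nt) %in% g1, 1L, 2L)
  myc <- ifelse(stats::runif(nt) < ifelse(nmf_group == 1L,
                                          cfg$myc_concordance,
                                          1 - cfg$myc_concordance), 1L, 0L)
  # per-tumor proliferation level correlated with true coupling
  zc <- as.numeric(scale(rho_true[seq_len(nt)]))
  prolif_t <- cfg$prolif_cor * zc +
    sqrt(max(0, 1 - cfg$prolif_cor^2)) * stats::rnorm(nt)
  prolif <- c(prolif_t, stats::rnorm(nn))

  ## ---- mRNA matrices ----------------------------------------------------
  Tind <- as.numeric(is_tumor)
  bio <- matrix(stats::rnorm(ng * ns, 0, cfg$bio_sd), ng, ns)
  mrna_bio <- mu_g + outer(dm, Tind) + bio
  mrna_bio[prolif_idx, ] <- mrna_bio[prolif_idx, , drop = FALSE] +
    cfg$prolif_effect * matrix(prolif, length(prolif_idx), ns, byrow = TRUE)
  mrna_obs <- mrna_bio + tau_g * matrix(stats::rnorm(ng * ns), ng, ns)
  zmat <- scale(mrna_bio)  # per-sample standardization across genes

  ## ---- protein latent pieces and fixed draws ---------------------------
  lib <- stats::rlnorm(ns, 0, cfg$lib_sd)
  blk <- matrix(0, ng, ns)
  blk[block_idx, which(is_tumor)[nmf_group == 1L]] <- cfg$block_lfc
  noise_mat <- sig_g * matrix(stats::rnorm(ng * ns), ng, ns)
  u_mat <- matrix(stats::runif(ng * ns), ng, ns)
  v_mat <- matrix(stats::runif(ng * ns), ng, ns)

  base_latent <- NULL
  rebuild_base <- function() a_g + outer(delta, Tind) + blk
  base_latent <- rebuild_base()

  make_counts <- function(cvec) {
    latent <- pmin(base_latent + sweep(zmat, 2L, cvec, "*") + noise_mat, 26)
    mu <- 2^latent * matrix(lib, ng, ns, byrow = TRUE)
    counts <- matrix(stats::qnbinom(u_mat, size = 1 / cfg$nb_dispersion,
                                    mu = mu), ng, ns)
    detp <- stats::plogis(cfg$detection_slope *
                            (latent - cfg$detection_midpoint))
    counts[v_mat >= detp] <- 0
    counts
  }

  calibrate_all <- function(idx_by_sample) {
    vapply(seq_len(ns), function(s)
      .calibrate_c(rho_true[s], base_latent[, s], zmat[, s], noise_mat[, s],
                   u_mat[, s], v_mat[, s], lib[s], mrna_obs[, s], cfg,
                   idx_by_sample[[s]]),
      numeric(1))
  }

  all_idx <- rep(list(seq_len(ng)), ns)
  cvec <- calibrate_all(all_idx)

  ## ---- fold-scale calibration ------------------------------------------
  # Median-of-ratios normalization anchors each sample near the smoothed
  # median of its fold distribution, so the mean fold change that
  # survives normalization is strongly attenuated relative to the latent
  # one, and the attenuation interacts with the coupling calibration
  # (stronger tumor fold signal requires a larger coupling scale, which
  # in turn moves the anchor).  As with coupling, the design targets are
  # *realized measured* quantities: the up-component shift is solved by a
  # damped secant on the measured mean background fold, where every
  # evaluation re-runs the coupling calibration so the feedback is
  # inside the loop; the 3'UTR shift (too small to move the anchor) is
  # then corrected additively.
  if (cfg$fold_calibrate && nn >= 6L && length(utr_idx) >= 10L) {
    tp <- seq_len(nn)          # tumor column of each pair
    np <- nt + seq_len(nn)     # matched normal column
    dbg <- isTRUE(getOption("proteoconcord.debug"))
    delta0 <- delta
    measure_folds <- function() {
      counts <- make_counts(cvec)
      om <- omics_matrix(counts, prots, samples, "counts")
      flt <- tryCatch(filter_features(om), error = function(e) NULL)
      if (is.null(flt)) return(NULL)
      sf <- size_factors(flt$matrix)
      rl <- rlog_like(flt$matrix, sf)
      gi <- match(rl$feature_ids, prots)
      d <- rl$values[, tp, drop = FALSE] - rl$values[, np, drop = FALSE]
      med <- apply(d, 1L, stats::median)
      inset <- gi %in% utr_idx
      c(bg = mean(med[!inset]), set = mean(med[inset]))
    }
    eval_at <- function(up_shift, utr_adj) {
      delta <<- delta0
      delta[up_idx] <<- delta0[up_idx] + up_shift
      delta[utr_idx] <<- delta0[utr_idx] + utr_adj
      base_latent <<- rebuild_base()
      cvec <<- calibrate_all(all_idx)
      measure_folds()
    }
    target_set <- log2(cfg$utr_protein_fc)
    # Gauss-Seidel on (up_shift, utr_adj): both measured responses are
    # re-evaluated jointly each round, so their cross-talk through the
    # anchor is inside the loop.
    up_prev <- 0; utr_adj <- 0
    m_prev <- eval_at(up_prev, utr_adj)
    if (!is.null(m_prev)) {
      slope <- 0.25
      up_cur <- min(max((target_bg - m_prev["bg"]) / slope, -2), 6)
      for (i in 1:5) {
        utr_adj <- utr_adj + (target_set - m_prev["set"])
        m_cur <- eval_at(up_cur, utr_adj)
        if (dbg) message(sprintf(
          "fold cal %d: up=%.2f utr=%.2f bg=%.3f set=%.3f",
          i, up_cur, utr_adj, m_cur["bg"], m_cur["set"]))
        if (is.null(m_cur)) { m_cur <- m_prev; break }
        if (abs(m_cur["bg"] - target_bg) < 0.02 &&
            abs(m_cur["set"] - target_set) < 0.02) { m_prev <- m_cur; break }
        if (abs(up_cur - up_prev) > 1e-6) {
          sl <- (m_cur["bg"] - m_prev["bg"]) / (up_cur - up_prev)
          if (is.finite(sl) && sl > 0.05) slope <- sl
        }
        step <- min(max((target_bg - m_cur["bg"]) / slope, -3), 3)
        up_prev <- up_cur; m_prev <- m_cur
        up_cur <- min(max(up_cur + step, 0), 10)
      }
    }
  }

  if (cfg$calibration_passes >= 2L) {
    counts <- make_counts(cvec)
    # recalibrate on the genes that survive each group's coverage filter,
    # i.e. the genes the concordance scorer will actually use
    kept_idx <- function(cols) {
      need <- ceiling(0.10 * length(cols))
      which(rowSums(counts[, cols, drop = FALSE] > 0) >= need)
    }
    kt <- kept_idx(which(is_tumor))
    kn <- kept_idx(which(!is_tumor))
    grp_idx <- lapply(seq_len(ns), function(s) if (is_tumor[s]) kt else kn)
    cvec <- calibrate_all(grp_idx)
  }
  counts <- make_counts(cvec)
  storage.mode(counts) <- "integer"

  ## ---- survival ---------------------------------------------------------
  rk <- rank(rho_true[seq_len(nt)], ties.method = "first")
  hz_group <- as.integer(floor(3 * (rk - 1) / nt))  # 0/1/2 tertiles
  log_rate <- log(cfg$hazard_base) + hz_group * cfg$hazard_log_hr_per_group +
    (nmf_group == 1L) * log(cfg$nmf_hazard_hr)
  t_ev <- stats::rexp(nt, rate = exp(log_rate))
  t_cn <- stats::runif(nt, cfg$censor_min, cfg$censor_max)
  surv_time <- pmax(0.1, round(pmin(t_ev, t_cn), 1))
  surv_event <- as.integer(t_ev <= t_cn)

  ## ---- assemble ---------------------------------------------------------
  pair_ids <- sprintf("PAIR%03d", seq_len(nn))
  clinical <- sample_table(data.frame(
    sample_id = samples,
    tissue = ifelse(is_tumor, "tumor", "normal"),
    pair_id = c(ifelse(seq_len(nt) <= nn, pair_ids, ""), pair_ids),
    subtype = c(subtype, rep(NA_character_, nn)),
    grade = c(grade, rep(NA_integer_, nn)),
    er_status = c(er, rep(NA_character_, nn)),
    race = c(race, rep(NA_character_, nn)),
    surv_time = c(surv_time, rep(NA_real_, nn)),
    surv_event = c(surv_event, rep(NA_integer_, nn)),
    stringsAsFactors = FALSE))

  cohort <- structure(list(
    protein = omics_matrix(counts, prots, samples, "counts"),
    mrna = omics_matrix(mrna_obs, genes, samples, "log_intensity"),
    clinical = clinical,
    pairs = pair_map(prots, genes)), class = "paired_cohort")

  planted_names <- if (cfg$n_planted_pathways > 0)
    sprintf("PLANTED_%02d", seq_len(cfg$n_planted_pathways)) else character(0)
  truth <- structure(list(
    coupling = rho_true,
    noise_scale = stats::setNames(cvec, samples),
    de_up = genes[up_idx], de_down = genes[dn_idx],
    utr_genes = genes[utr_idx], ecm_genes = genes[ecm_idx],
    block_genes = genes[block_idx], prolif_genes = genes[prolif_idx],
    mrna_de_up = genes[m_up_idx], mrna_de_down = genes[m_dn_idx],
    stability = data.frame(gene_id = genes, protein_stable = prot_stable,
                           mrna_stable = mrna_stable,
                           stringsAsFactors = FALSE),
    planted_pathways = planted_names,
    nmf_group = stats::setNames(nmf_group, tum_ids),
    myc_signature = stats::setNames(myc, tum_ids),
    hazard_group = stats::setNames(hz_group, tum_ids),
    prolif_level = stats::setNames(prolif, samples),
    gene_ids = genes,
    internals = list(a_g = a_g, mu_g = mu_g, delta = delta, lib = lib,
                     sigma_g = sig_g, tau_g = tau_g)),
    class = "synthetic_truth")
  list(cohort = cohort, truth = truth)
}

#' @export
print.paired_cohort <- function(x, ...) {
  cat(sprintf("<paired_cohort> %d proteins, %d genes, %d tumors + %d normals\n",
              length(x$protein$feature_ids), length(x$mrna$feature_ids),
              sum(x$clinical$tissue == "tumor"),
              sum(x$clinical$tissue == "normal")))
  invisible(x)
}

#' Generate gene sets aligned with a synthetic cohort
#'
#' Builds `n_pathways` sets of `pathway_size` genes.  The first
#' `n_planted_pathways` sets ("PLANTED_xx") are drawn from genes that are
#' stable in both omics, i.e. genes whose across-subject protein-mRNA
#' concordance is high by construction; the remaining sets ("RANDOM_xx")
#' are drawn uniformly from all genes.
#'
#' @param cfg the [sim_config()] used for the cohort.
#' @param truth the `synthetic_truth` from [generate_cohort()].
#' @return a [gene_set_collection()].
#' @export
generate_gene_sets <- function(cfg, truth) {
  stopifnot(inherits(cfg, "sim_config"), inherits(truth, "synthetic_truth"))
  if (cfg$pathway_size > length(truth$gene_ids))
    stop("pathway_size exceeds the number of genes")
  set.seed(cfg$seed + 1L)
  stable_pool <- truth$stability$gene_id[truth$stability$protein_stable &
                                           truth$stability$mrna_stable]
  if (cfg$n_planted_pathways > 0 && length(stable_pool) < cfg$pathway_size)
    stop("too few stable-stable genes to plant pathways of this size")
  sets <- list()
  for (i in seq_len(cfg$n_planted_pathways))
    sets[[sprintf("PLANTED_%02d", i)]] <- sample(stable_pool, cfg$pathway_size)
  for (i in seq_len(cfg$n_pathways - cfg$n_planted_pathways))
    sets[[sprintf("RANDOM_%02d", i)]] <- sample(truth$gene_ids,
                                                cfg$pathway_size)
  gene_set_collection(sets)
}

#' Write a synthetic cohort to a directory
#'
#' Emits the pipeline's on-disk formats: `protein_counts.tsv`,
#' `mrna_log2.tsv`, `pairs.tsv`, `clinical.csv`, `sets.gmt`,
#' `annotations/*.txt` (3'UTR, ECM, block, proliferation gene lists and
#' per-tumor Myc flags) and `truth.json`.
#'
#' @param cohort a `paired_cohort`.
#' @param truth the matching `synthetic_truth`.
#' @param sets a `gene_set_collection` (optional).
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, truth, sets = NULL, dir) {
  dir.create(file.path(dir, "annotations"), recursive = TRUE,
             showWarnings = FALSE)
  write_matrix(cohort$protein, file.path(dir, "protein_counts.tsv"))
  write_matrix(cohort$mrna, file.path(dir, "mrna_log2.tsv"))
  write_pair_map(cohort$pairs, file.path(dir, "pairs.tsv"))
  write_clinical(cohort$clinical, file.path(dir, "clinical.csv"))
  if (!is.null(sets)) write_gene_sets(sets, file.path(dir, "sets.gmt"))
  ann <- file.path(dir, "annotations")
  writeLines(truth$utr_genes, file.path(ann, "utr_genes.txt"))
  writeLines(truth$ecm_genes, file.path(ann, "ecm_genes.txt"))
  writeLines(truth$block_genes, file.path(ann, "block_genes.txt"))
  writeLines(truth$prolif_genes, file.path(ann, "prolif_genes.txt"))
  writeLines(names(truth$myc_signature)[truth$myc_signature == 1L],
             file.path(ann, "myc_positive_samples.txt"))
  tr <- truth
  class(tr) <- NULL
  jsonlite::write_json(tr, file.path(dir, "truth.json"), auto_unbox = FALSE,
                       digits = NA)
  invisible(dir)
}
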