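#' Configuration for synthetic tumor-cohort generation
#'
#' Describes the data-generating process the driver test assumes: per
#' sample a purity drawn from a Beta distribution; per gene and sample a
#' Bernoulli mutation with a class drawn from `class_mix`; a clonal or
#' subclonal cancer cell fraction; a tumor total copy number; DNA read
#' counts binomial around the CCF-implied DNA VAF; and RNA read counts
#' beta-binomial (over-dispersion `rho_rna`) around the DNA-implied
#' allelic fraction, shifted upward by the planted effect `delta` for
#' nonsynonymous mutations of driver genes and suppressed by the
#' NMD factor for nonsense mutations. Per-gene RNA depth tiers (including
#' a zero-expression tier) emulate the expression spectrum; driver genes
#' are placed in expressed tiers, since the method can only see drivers
#' whose transcripts are expressed.
#'
#' @param n_samples samples in the cohort (default 100).
#' @param n_genes genes (default 200).
#' @param drivers data.frame with one row per planted driver gene:
#'   `delta` (additive RNA-VAF elevation in `[0, 1]`) and `rate_mult`
#'   (mutation-rate multiplier); `NULL` for a null cohort.
#' @param base_mut_rate per-gene per-sample mutation probability
#'   (default 0.04).
#' @param class_mix probabilities over synonymous / missense / nonsense /
#'   splice_site (must sum to 1).
#' @param purity_shape Beta shape parameters for purity (default
#'   `c(8, 4)`, mean 2/3).
#' @param rna_tiers per-tier probabilities and negative-binomial depth
#'   parameters, including a zero-expression tier.
#' @param dna_depth_mu,dna_depth_size negative-binomial DNA depth.
#' @param rho_rna beta-binomial over-dispersion of RNA counts
#'   (default 0.05, matching the ASE test's assumption).
#' @param nmd_effect 10 true per-decile NMD suppression factors applied to
#'   nonsense-mutation RNA VAFs (decile of the simulated NMD score).
#' @param ccf_clonal_prob probability a mutation is clonal (default 0.7);
#'   subclonal CCFs are Uniform(0.2, 0.8).
#' @param tcn_probs probabilities of tumor total copy number 1-4.
#' @param seed integer seed; the generator is byte-deterministic given
#'   the config.
#' @return A `simulation_config` list.
#' @export
simulation_config <- function(n_samples = 100L, n_genes = 200L,
                              drivers = NULL, base_mut_rate = 0.04,
                              class_mix = c(synonymous = 0.30,
                                            missense = 0.55,
                                            nonsense = 0.10,
                                            splice_site = 0.05),
                              purity_shape = c(8, 4),
                              rna_tiers = list(
                                prob = c(zero = 0.10, low = 0.30,
                                         mid = 0.40, high = 0.20),
                                mu = c(zero = 0, low = 10, mid = 40,
                                       high = 150),
                                size = c(zero = 1, low = 2, mid = 3,
                                         high = 3)),
                              dna_depth_mu = 80, dna_depth_size = 8,
                              rho_rna = 0.05,
                              nmd_effect = seq(0.9, 0.3,
                                               length.out = 10),
                              ccf_clonal_prob = 0.7,
                              tcn_probs = c(0.15, 0.55, 0.20, 0.10),
                              seed = 1L) {
  stopifnot(abs(sum(class_mix) - 1) < 1e-8,
            abs(sum(rna_tiers$prob) - 1) < 1e-8,
            abs(sum(tcn_probs) - 1) < 1e-8,
            length(nmd_effect) == 10, all(nmd_effect > 0))
  if (!is.null(drivers)) {
    stopifnot(is.data.frame(drivers),
              all(c("delta", "rate_mult") %in% names(drivers)),
              all(drivers$delta >= 0 & drivers$delta <= 1),
              nrow(drivers) < n_genes)
  }
  structure(as.list(environment()), class = "simulation_config")
}

# beta-binomial draws with mean mu and intraclass correlation rho
.rbetabinom <- function(n, size, mu, rho) {
  mu <- pmin(pmax(mu, 0), 1)
  out <- integer(n)
  inner <- mu > 0 & mu < 1 & size > 0
  if (any(inner)) {
    a <- mu[inner] * (1 - rho) / rho
    b <- (1 - mu[inner]) * (1 - rho) / rho
    p <- stats::rbeta(sum(inner), a, b)
    out[inner] <- stats::rbinom(sum(inner), size[inner], p)
  }
  out[mu >= 1] <- size[mu >= 1]
  out
}

#' Generate a synthetic cohort with known ground truth
#'
#' @param config a [simulation_config()].
#' @return List: `cohort` (a `cohort_table`), `truth` (per-mutation
#'   expected VAFs and planted effects), `gene_truth` (per-gene `delta`,
#'   `rate_mult`, expression tier), `annotation` (a `gene_annotation`
#'   whose CGC list holds the planted driver genes).
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed)
  n_drv <- if (is.null(config$drivers)) 0L else nrow(config$drivers)
  gene_id <- c(if (n_drv) sprintf("driver%02d", seq_len(n_drv)),
               sprintf("gene%04d", seq_len(config$n_genes - n_drv)))
  delta <- c(if (n_drv) config$drivers$delta, rep(0, config$n_genes - n_drv))
  rate_mult <- c(if (n_drv) config$drivers$rate_mult,
                 rep(1, config$n_genes - n_drv))
  tier_names <- names(config$rna_tiers$prob)
  tier <- sample(tier_names, config$n_genes, replace = TRUE,
                 prob = config$rna_tiers$prob)
  if (n_drv) {  # drivers are expressed genes
    expr_tiers <- setdiff(tier_names, "zero")
    p_expr <- config$rna_tiers$prob[expr_tiers]
    tier[seq_len(n_drv)] <- sample(expr_tiers, n_drv, replace = TRUE,
                                   prob = p_expr / sum(p_expr))
  }
  chrom <- paste0("chr", rep_len(1:22, config$n_genes))
  base_pos <- seq_len(config$n_genes) * 1000000L
  sample_id <- sprintf("s%04d", seq_len(config$n_samples))
  purity <- stats::rbeta(config$n_samples, config$purity_shape[1],
                         config$purity_shape[2])
  recs <- vector("list", config$n_genes)
  for (g in seq_len(config$n_genes)) {
    p_mut <- min(1, config$base_mut_rate * rate_mult[g])
    hit <- which(stats::runif(config$n_samples) < p_mut)
    if (!length(hit)) next
    m <- length(hit)
    vc <- sample(names(config$class_mix), m, replace = TRUE,
                 prob = config$class_mix)
    clonal <- stats::runif(m) < config$ccf_clonal_prob
    ccf <- ifelse(clonal, 1, stats::runif(m, 0.2, 0.8))
    tcn <- sample(1:4, m, replace = TRUE, prob = config$tcn_probs)
    pur <- purity[hit]
    exp_dna_vaf <- ccf * pur / ((1 - pur) * 2 + pur * tcn)
    dna_depth <- pmax(1L, stats::rnbinom(m, mu = config$dna_depth_mu,
                                         size = config$dna_depth_size))
    dna_alt <- stats::rbinom(m, dna_depth, exp_dna_vaf)
    shift <- ifelse(vc != "synonymous", delta[g], 0)
    exp_rna_vaf <- pmin(1, pmax(0, exp_dna_vaf + shift))
    nmd_score <- ifelse(vc == "nonsense", stats::runif(m), NA_real_)
    is_non <- vc == "nonsense"
    if (any(is_non)) {
      dec <- pmin(10L, floor(nmd_score[is_non] * 10) + 1L)
      exp_rna_vaf[is_non] <- exp_rna_vaf[is_non] * config$nmd_effect[dec]
    }
    rna_depth <- if (tier[g] == "zero") rep(0L, m) else
      stats::rnbinom(m, mu = config$rna_tiers$mu[[tier[g]]],
                     size = config$rna_tiers$size[[tier[g]]])
    rna_alt <- .rbetabinom(m, rna_depth, exp_rna_vaf, config$rho_rna)
    recs[[g]] <- data.frame(
      sample_id = sample_id[hit], gene = gene_id[g], chrom = chrom[g],
      pos = base_pos[g] + hit * 10L, ref_allele = "C", alt_allele = "T",
      var_class = vc, dna_vaf = ifelse(dna_depth > 0, dna_alt / dna_depth, 0),
      dna_alt = dna_alt, dna_depth = dna_depth,
      rna_alt = as.integer(rna_alt),
      rna_ref = as.integer(rna_depth - rna_alt),
      nmd_score = nmd_score, purity = pur, ncn = 2L, tcn = tcn,
      true_delta = shift, exp_dna_vaf = exp_dna_vaf,
      exp_rna_vaf = exp_rna_vaf, true_ccf = ccf, true_clonal = clonal,
      stringsAsFactors = FALSE)
  }
  all <- do.call(rbind, recs)
  truth_cols <- c("true_delta", "exp_dna_vaf", "exp_rna_vaf", "true_ccf",
                  "true_clonal")
  truth <- cbind(all[c("sample_id", "gene", "chrom", "pos", "var_class")],
                 all[truth_cols])
  cohort <- cohort_table(all[setdiff(names(all), truth_cols)],
                         cancer_type = "SIM")
  gene_truth <- data.frame(gene = gene_id, delta = delta,
                           rate_mult = rate_mult, tier = tier,
                           stringsAsFactors = FALSE)
  annotation <- structure(list(cgc_genes = gene_id[delta > 0],
                               oncogenes = character(0),
                               tsgs = character(0)),
                          class = "gene_annotation")
  list(cohort = cohort, truth = truth, gene_truth = gene_truth,
       annotation = annotation)
}

#' Calibration experiment: type-I error, power, effect recovery
#'
#' Runs the full driver pipeline on `n_reps` independently seeded
#' replicates of a simulation configuration and summarises: the fraction
#' of null genes (planted `delta = 0`) reaching `p_geomean < 0.05`
#' (empirical type-I error), the fraction of planted drivers called at
#' `q < q_thresh` (power; also reported restricted to drivers mutated in
#' at least `min_driver_samples` samples), and the slope of estimated
#' effect size on true `delta` among drivers (effect recovery).
#'
#' @param config a [simulation_config()]; replicate `r` uses seed
#'   `config$seed + 1000 * r`.
#' @param n_reps number of replicates (default 2).
#' @param mode passed to [driver_analysis()].
#' @param q_thresh driver-call threshold (default 0.25).
#' @param min_driver_samples mutated-sample condition for the restricted
#'   power estimate (default 5).
#' @return List with `n_null_tested`, `type1_rate`, `n_drivers_tested`,
#'   `power`, `power_min_samples`, `effect_slope`, and the pooled per-gene
#'   table `genes`.
#' @export
calibration_experiment <- function(config, n_reps = 2L,
                                   mode = "per_class_min",
                                   q_thresh = 0.25,
                                   min_driver_samples = 5L) {
  pooled <- list()
  for (r in seq_len(n_reps)) {
    cfg <- config
    cfg$seed <- config$seed + 1000L * r
    sim <- simulate_cohort(cfg)
    res <- driver_analysis(sim$cohort, sim$annotation, mode = mode,
                           q_thresh = q_thresh, seed = cfg$seed + 1L)
    if (!nrow(res)) next
    res$rep <- r
    res$delta <- sim$gene_truth$delta[match(res$gene, sim$gene_truth$gene)]
    # mutated samples in the method's own sense: samples carrying a
    # nonsynonymous mutation in the gene
    nonsyn <- sim$cohort$var_class %in% NONSYN_CLASSES
    ns <- tapply(sim$cohort$sample_id[nonsyn], sim$cohort$gene[nonsyn],
                 function(x) length(unique(x)))
    res$n_mut_samples <- as.integer(ns[res$gene])
    pooled[[r]] <- res[c("rep", "gene", "class_subset", "n_case",
                         "n_mut_samples", "effect_size", "p_geomean",
                         "q_value", "driver_flag", "delta")]
  }
  genes <- do.call(rbind, pooled)
  rownames(genes) <- NULL
  null <- genes[genes$delta == 0, , drop = FALSE]
  drv <- genes[genes$delta > 0, , drop = FALSE]
  drv_min <- drv[drv$n_mut_samples >= min_driver_samples, , drop = FALSE]
  slope <- if (nrow(drv) >= 2 && length(unique(drv$delta)) >= 2)
    unname(stats::coef(stats::lm(effect_size ~ delta, data = drv))["delta"])
  else NA_real_
  list(n_null_tested = nrow(null),
       type1_rate = if (nrow(null)) mean(null$p_geomean < 0.05) else NA_real_,
       n_drivers_tested = nrow(drv),
       power = if (nrow(drv)) mean(drv$driver_flag) else NA_real_,
       power_min_samples = if (nrow(drv_min)) mean(drv_min$driver_flag)
       else NA_real_,
       n_drivers_min_samples = nrow(drv_min),
       effect_slope = slope,
       genes = genes)
}
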