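#' Weighted one-sided comparison of case versus background RNA VAFs
#'
#' Fits the weighted linear model `vaf ~ group` (group = 1 for the gene's
#' case mutations, 0 for the background) with the supplied per-mutation
#' depth weights and returns the group coefficient and the upper-tail
#' (case above background) one-sided p value of its t statistic on
#' `n - 2` residual degrees of freedom. Positive selection elevates the
#' RNA VAF of driver mutations, so the directional alternative is
#' case > background.
#'
#' @param case_vaf,bg_vaf RNA VAFs of the case and background mutations.
#' @param case_weight,bg_weight positive per-mutation weights (default 1).
#' @return A list: `effect_size`, `p_one_sided`, `degenerate`.
#' @export
weighted_group_test <- function(case_vaf, bg_vaf,
                                case_weight = rep(1, length(case_vaf)),
                                bg_weight = rep(1, length(bg_vaf))) {
  if (length(case_vaf) < 2) stop("need at least 2 case mutations")
  if (length(bg_vaf) < 1) stop("need at least 1 background mutation")
  y <- c(case_vaf, bg_vaf)
  g <- c(rep(1, length(case_vaf)), rep(0, length(bg_vaf)))
  w <- c(case_weight, bg_weight)
  if (max(y) - min(y) < .Machine$double.eps)
    return(list(effect_size = 0, p_one_sided = 0.5, degenerate = TRUE))
  fit <- stats::lm(y ~ g, weights = w)
  est <- unname(stats::coef(fit)["g"])
  # a residual-free fit is handled below, not worth a warning
  se <- sqrt(diag(suppressWarnings(stats::vcov(fit))))["g"]
  if (!is.finite(se) || se <= 0) {
    p <- if (est > 0) 0 else if (est < 0) 1 else 0.5
  } else {
    p <- stats::pt(est / se, df = fit$df.residual, lower.tail = FALSE)
  }
  list(effect_size = est, p_one_sided = unname(p), degenerate = FALSE)
}

#' Geometric mean of bootstrap p values
#'
#' @param ps p values in `(0, 1]`; floored at `1e-300` before logs.
#' @return `exp(mean(log(ps)))`.
#' @export
geometric_mean_p <- function(ps) {
  if (!length(ps)) stop("empty p-value vector")
  exp(mean(log(pmax(ps, 1e-300))))
}

#' Benjamini-Hochberg adjusted q values
#'
#' Standard step-up false-discovery-rate adjustment (delegates to
#' [stats::p.adjust()] with `method = "BH"`).
#'
#' @param ps p values in `[0, 1]`.
#' @return q values, same length and order.
#' @export
bh_qvalues <- function(ps) {
  stopifnot(all(ps >= 0 & ps <= 1, na.rm = TRUE))
  stats::p.adjust(ps, method = "BH")
}

# synonymous-provenance tiers (k-scaled); tier-iv draws are already on the
# nonsynonymous scale
.SYN_TIERS <- c("i_same_sample", "ii_mutated_samples", "iii_cohort",
                "vi_gene_syn")

#' Bootstrapped gene-level test
#'
#' Repeats background sampling, synonymous scaling and the weighted group
#' test `B` times (default 25) with independent draws, then aggregates:
#' the gene's p value is the geometric mean of the bootstrap p values and
#' its effect size the mean of the bootstrap coefficients.
#'
#' @param gene tested gene symbol.
#' @param class_subset one of `missense_only`, `nonsense_only`,
#'   `splice_only`, `all_nonsyn`.
#' @param cohort a weighted, NMD-scaled `cohort_table`.
#' @param plan a `sampling_plan` (carries the synonymous scaling factor k).
#' @param B bootstrap replicates (default 25).
#' @param seed optional seed for this gene's draws.
#' @return One-row data.frame (`gene`, `class_subset`, `n_case`,
#'   `effect_size`, `p_geomean`, list-columns `p_boot` and `tier_counts`),
#'   or `NULL` with attribute `reason` when no background is available.
#' @export
bootstrap_gene_test <- function(gene, class_subset, cohort, plan, B = 25L,
                                seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  classes <- .subset_classes(class_subset)
  case <- cohort$gene == gene & cohort$var_class %in% classes
  if (sum(case) < 2) stop("fewer than 2 case mutations for ", gene)
  case_vaf <- cohort$rna_vaf[case]
  case_w <- cohort$weight[case]
  ps <- numeric(B)
  effects <- numeric(B)
  tier_counts <- integer(0)
  incomplete <- 0L
  for (b in seq_len(B)) {
    draw <- tryCatch(sample_background(gene, class_subset, cohort, plan),
                     rv_no_background = function(e) NULL)
    if (is.null(draw)) {
      out <- NULL
      attr(out, "reason") <- paste0("no background available for ", gene)
      return(out)
    }
    bg_vaf <- draw$mutations$rna_vaf
    syn <- draw$tier %in% .SYN_TIERS
    bg_vaf[syn] <- apply_syn_scaling(bg_vaf[syn], plan$k_syn_scale)
    res <- weighted_group_test(case_vaf, bg_vaf, case_w,
                               draw$mutations$weight)
    ps[b] <- max(res$p_one_sided, 1e-300)  # keep p in (0, 1] for the logs
    effects[b] <- res$effect_size
    tc <- table(draw$tier)
    for (nm in names(tc))
      tier_counts[nm] <- (if (nm %in% names(tier_counts))
        tier_counts[[nm]] else 0L) + tc[[nm]]
    incomplete <- incomplete + draw$incomplete
  }
  data.frame(gene = gene, class_subset = class_subset,
             n_case = sum(case),
             effect_size = mean(effects),
             p_geomean = geometric_mean_p(ps),
             p_boot = I(list(ps)),
             tier_counts = I(list(tier_counts)),
             n_incomplete = incomplete,
             stringsAsFactors = FALSE)
}

#' Run the driver test across all testable genes of one cancer type
#'
#' For each testable gene, class-specific tests (missense-only,
#' nonsense-only, splice-only) are run wherever the gene has at least two
#' mutations of that class, separately as well as together (the
#' all-nonsynonymous test). In `per_class_min` mode (cancer-type-specific
#' analysis) the smallest p value over the tests performed is reported;
#' in `combined` mode (pan-cancer analysis) the all-nonsynonymous test is
#' reported. Reported p values are then Benjamini-Hochberg corrected
#' within the run and genes with q < `q_thresh` flagged as putative
#' drivers.
#'
#' @param cohort a weighted, NMD-scaled `cohort_table`.
#' @param annotation a `gene_annotation`.
#' @param mode `"per_class_min"` or `"combined"`.
#' @param min_nonsyn,min_depth testability thresholds (defaults 2 and 8).
#' @param B bootstrap replicates per test (default 25).
#' @param q_thresh driver-call threshold on the q value (default 0.25).
#' @param min_bg_depth,include_gene_syn,rate_cap background sampling
#'   settings, see [sampling_plan()].
#' @param k_grid grid for [compute_syn_scaling_factor()].
#' @param seed master seed; all sampling downstream is reproducible
#'   bit-for-bit given the same seed and inputs.
#' @return data.frame of gene results with columns `gene`, `class_subset`,
#'   `n_case`/`n_mutations`, `effect_size`, `p_geomean`, `q_value`,
#'   `driver_flag`; attributes `k`, `rate`, `skipped`.
#' @export
run_cancer_type <- function(cohort, annotation,
                            mode = c("per_class_min", "combined"),
                            min_nonsyn = 2L, min_depth = 8L, B = 25L,
                            q_thresh = 0.25, min_bg_depth = 8L,
                            include_gene_syn = FALSE, rate_cap = 0.202,
                            k_grid = seq(0.25, 4, by = 0.001),
                            seed = NULL) {
  mode <- match.arg(mode)
  if (!is.null(seed)) set.seed(seed)
  testable <- select_testable_genes(cohort, min_nonsyn, min_depth)
  empty <- data.frame(gene = character(0), class_subset = character(0),
                      n_case = integer(0), n_mutations = integer(0),
                      effect_size = numeric(0), p_geomean = numeric(0),
                      q_value = numeric(0), driver_flag = logical(0))
  if (!length(testable)) {
    warning("no testable genes in cohort")
    return(empty)
  }
  k <- compute_syn_scaling_factor(cohort, testable, annotation,
                                  min_bg_depth = min_bg_depth,
                                  k_grid = k_grid)
  plan <- sampling_plan(n_cohort(cohort), k = k,
                        min_bg_depth = min_bg_depth,
                        include_gene_syn = include_gene_syn,
                        rate_cap = rate_cap)
  rows <- list()
  skipped <- character(0)
  class_subsets <- c(missense_only = "missense", nonsense_only = "nonsense",
                     splice_only = "splice_site")
  for (g in testable) {
    in_gene <- cohort$gene == g
    counts <- vapply(class_subsets, function(cl)
      sum(in_gene & cohort$var_class == cl), 0L)
    res <- NULL
    if (mode == "per_class_min") {
      avail <- names(class_subsets)[counts >= min_nonsyn]
      cand <- list()
      for (cs in avail)
        cand[[cs]] <- bootstrap_gene_test(g, cs, cohort, plan, B = B)
      # the all-nonsynonymous test always runs alongside the class tests
      # ("separately, as well as together"); with a single represented
      # class it coincides with that class's test and is the fallback
      if (!length(avail) || sum(counts) > max(counts))
        cand[["all_nonsyn"]] <- bootstrap_gene_test(g, "all_nonsyn", cohort,
                                                    plan, B = B)
      cand <- Filter(Negate(is.null), cand)
      if (length(cand)) {
        pvals <- vapply(cand, function(x) x$p_geomean, 0)
        res <- cand[[which.min(pvals)]]
      }
    } else {
      res <- bootstrap_gene_test(g, "all_nonsyn", cohort, plan, B = B)
    }
    if (is.null(res)) skipped <- c(skipped, g) else rows[[g]] <- res
  }
  if (!length(rows)) {
    warning("all testable genes were skipped (no background available)")
    return(empty)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out$n_mutations <- out$n_case
  out$q_value <- bh_qvalues(out$p_geomean)
  out$driver_flag <- out$q_value < q_thresh
  attr(out, "k") <- k
  attr(out, "rate") <- plan$rate
  attr(out, "skipped") <- skipped
  out
}

#' End-to-end driver analysis on a raw cohort
#'
#' Convenience wrapper: preprocessing ([preprocess_cohort()]), NMD model
#' fitting and scaling ([fit_nmd_model()], [apply_nmd_scaling()]; skipped
#' with a warning when the cohort lacks expressed missense mutations), and
#' the per-gene driver test ([run_cancer_type()]).
#'
#' @inheritParams run_cancer_type
#' @param cohort a raw `cohort_table`.
#' @param cap per-(sample, gene) mutation cap (default 3).
#' @param depth_cap_quantile RNA-depth cap percentile for weights.
#' @param nmd_factor_floor floor on NMD divisors (default 0.05).
#' @return As [run_cancer_type()], with attribute `manifest` describing
#'   the run (settings, seed, k, rate, skipped genes).
#' @export
driver_analysis <- function(cohort, annotation,
                            mode = c("per_class_min", "combined"),
                            cap = 3L, depth_cap_quantile = 0.9,
                            min_nonsyn = 2L, min_depth = 8L, B = 25L,
                            q_thresh = 0.25, min_bg_depth = 8L,
                            include_gene_syn = FALSE, rate_cap = 0.202,
                            nmd_factor_floor = 0.05, seed = NULL) {
  mode <- match.arg(mode)
  if (!is.null(seed)) set.seed(seed)
  wc <- preprocess_cohort(cohort, cap = cap,
                          depth_cap_quantile = depth_cap_quantile)
  nmd <- tryCatch(fit_nmd_model(wc),
                  error = function(e) {
                    warning("NMD scaling skipped: ", conditionMessage(e))
                    NULL
                  })
  if (!is.null(nmd))
    wc <- apply_nmd_scaling(wc, nmd, factor_floor = nmd_factor_floor)
  res <- run_cancer_type(wc, annotation, mode = mode,
                         min_nonsyn = min_nonsyn, min_depth = min_depth,
                         B = B, q_thresh = q_thresh,
                         min_bg_depth = min_bg_depth,
                         include_gene_syn = include_gene_syn,
                         rate_cap = rate_cap)
  attr(res, "manifest") <- list(
    cancer_type = attr(cohort, "cancer_type"),
    n_cohort = n_cohort(cohort), mode = mode, seed = seed,
    cap = cap, depth_cap_quantile = depth_cap_quantile,
    min_nonsyn = min_nonsyn, min_depth = min_depth, B = B,
    q_thresh = q_thresh, min_bg_depth = min_bg_depth,
    include_gene_syn = include_gene_syn, rate_cap = rate_cap,
    nmd_global_only = if (is.null(nmd)) NA else nmd$global_only,
    k = attr(res, "k"), rate = attr(res, "rate"),
    skipped = attr(res, "skipped"),
    package_version = as.character(utils::packageVersion("rnadriver")))
  res
}
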