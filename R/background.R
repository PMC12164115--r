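#' Cohort-scaled exponential sampling rate
#'
#' The number of synonymous background mutations drawn per nonsynonymous
#' mutation grows exponentially with the number of mutated samples,
#' governed by a cohort-specific rate chosen so that a gene mutated in 5%
#' of the cohort receives 10 background mutations per case mutation:
#' `rate = ln(10) / (0.05 * cohort_size)`. The rate is capped (default
#' 0.202, the largest value for which a gene with two mutated samples still
#' receives a single background mutation per case mutation) to avoid
#' extreme rates in small cohorts.
#'
#' @param cohort_size number of samples in the cohort (>= 2).
#' @param cap upper bound on the rate (default 0.202).
#' @return The sampling rate.
#' @export
compute_sampling_rate <- function(cohort_size, cap = 0.202) {
  if (!is.finite(cohort_size) || cohort_size < 2)
    stop("cohort_size must be >= 2")
  min(log(10) / (0.05 * cohort_size), cap)
}

#' Background mutations sampled per case mutation
#'
#' `n = min(round(exp(rate * n_samples)), 2 * n_samples)`, where
#' `n_samples` is the number of samples carrying a nonsynonymous mutation
#' in the tested gene. Rounding is round-half-to-even (R's `round`).
#'
#' @param rate sampling rate from [compute_sampling_rate()].
#' @param n_samples number of mutated samples (>= 1).
#' @return Integer number of background mutations per case mutation.
#' @export
n_background_per_mutation <- function(rate, n_samples) {
  if (n_samples < 1) stop("n_samples must be >= 1")
  as.integer(min(round(exp(rate * n_samples)), 2 * n_samples))
}

#' Bundle the background-sampling parameters
#'
#' @param cohort_size number of samples in the cohort.
#' @param k synonymous scaling factor (see
#'   [compute_syn_scaling_factor()]); default 1.
#' @param min_bg_depth minimum RNA depth for background mutations
#'   (default 8).
#' @param include_gene_syn include the tested gene's own synonymous
#'   mutations as an extra background tier (default FALSE).
#' @param rate_cap cap passed to [compute_sampling_rate()].
#' @return A `sampling_plan` list.
#' @export
sampling_plan <- function(cohort_size, k = 1, min_bg_depth = 8L,
                          include_gene_syn = FALSE, rate_cap = 0.202) {
  structure(list(rate = compute_sampling_rate(cohort_size, rate_cap),
                 k_syn_scale = k, min_bg_depth = min_bg_depth,
                 include_gene_syn = include_gene_syn),
            class = "sampling_plan")
}

#' Synonymous background scaling factor
#'
#' Synonymous background VAFs differ systematically from the nonsynonymous
#' VAFs of tested genes. A multiplicative factor `k` is chosen on a grid to
#' minimise `|k*mean(S) - mean(G)| + |k*median(S) - median(G)|`, where `S`
#' are the RNA VAFs of depth-eligible synonymous mutations and `G` the
#' per-gene mean nonsynonymous RNA VAFs of tested genes outside the CGC
#' list (so known cancer genes do not pull the background upward). Ties
#' resolve to the smallest `k`.
#'
#' @param cohort a weighted `cohort_table`.
#' @param tested_genes genes selected by [select_testable_genes()].
#' @param annotation a `gene_annotation` (for CGC membership).
#' @param min_bg_depth minimum RNA depth for background-eligible synonymous
#'   mutations (default 8).
#' @param k_grid search grid (default `seq(0.25, 4, by = 0.001)`).
#' @return The optimal scaling factor `k`.
#' @export
compute_syn_scaling_factor <- function(cohort, tested_genes, annotation,
                                       min_bg_depth = 8L,
                                       k_grid = seq(0.25, 4, by = 0.001)) {
  non_cgc <- setdiff(tested_genes, annotation$cgc_genes)
  if (!length(non_cgc)) {
    warning("no non-CGC tested genes; synonymous scaling factor set to 1")
    return(1)
  }
  syn <- cohort$var_class == "synonymous" & cohort$rna_depth >= min_bg_depth
  s_vaf <- cohort$rna_vaf[syn]
  if (length(s_vaf) < 10) {
    warning("fewer than 10 background-eligible synonymous mutations; ",
            "synonymous scaling factor set to 1")
    return(1)
  }
  case <- cohort$gene %in% non_cgc & cohort$var_class %in% NONSYN_CLASSES
  g_means <- tapply(cohort$rna_vaf[case], cohort$gene[case], mean)
  obj <- abs(k_grid * mean(s_vaf) - mean(g_means)) +
    abs(k_grid * stats::median(s_vaf) - stats::median(g_means))
  k_grid[which.min(obj)]  # which.min takes the first (smallest k) on ties
}

#' Apply the synonymous scaling factor to background VAFs
#'
#' @param vaf numeric VAFs in `[0, 1]`.
#' @param k positive scaling factor.
#' @return `min(1, vaf * k)`.
#' @export
apply_syn_scaling <- function(vaf, k) {
  if (!is.finite(k) || k <= 0) stop("k must be positive")
  pmin(1, vaf * k)
}

# class subsets -> variant classes
.subset_classes <- function(class_subset) {
  switch(class_subset,
         missense_only = "missense",
         nonsense_only = "nonsense",
         splice_only = "splice_site",
         all_nonsyn = NONSYN_CLASSES,
         stop("unknown class subset: ", class_subset))
}

#' Hierarchically sample a background mutation set for one gene
#'
#' For each tumor sample carrying a case mutation (a mutation of the tested
#' class within the gene of interest), `n` background mutations per case
#' mutation in that sample are drawn without replacement, filling the quota
#' tier by tier: (i) synonymous mutations from that sample; (ii) synonymous
#' mutations from the other mutated samples; (iii) synonymous mutations
#' from any cohort sample; optionally (vi) the tested gene's own synonymous
#' mutations; (iv) nonsynonymous mutations of the tested class from that
#' sample (never from the tested gene); (v) if the quota still cannot be
#' met, the incomplete background is used. Synonymous tiers require an RNA
#' depth of at least `plan$min_bg_depth`; so do tier-iv draws, for
#' consistency. Sampling per draw is without replacement across all tiers
#' and samples: no mutation appears twice in one draw.
#'
#' This per-sample matching controls for sample-level confounders such as
#' tumor purity and the tumor/normal expression balance.
#'
#' @param gene tested gene symbol.
#' @param class_subset one of `missense_only`, `nonsense_only`,
#'   `splice_only`, `all_nonsyn`.
#' @param cohort a weighted `cohort_table` (NMD-scaled VAFs).
#' @param plan a `sampling_plan`.
#' @param seed optional seed; when `NULL` the current RNG state is used
#'   (draws are reproducible under a caller-set master seed).
#' @return A `background_draw` list: `mutations` (rows of the cohort),
#'   `tier` (provenance per drawn mutation), `target_n` (total quota),
#'   `n_per_mutation`, `incomplete`.
#' @export
sample_background <- function(gene, class_subset, cohort, plan,
                              seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  classes <- .subset_classes(class_subset)
  in_gene <- cohort$gene == gene
  case_idx <- which(in_gene & cohort$var_class %in% classes)
  if (!length(case_idx)) stop("no case mutations for ", gene)
  nonsyn_samples <- unique(cohort$sample_id[in_gene &
                                              cohort$var_class %in%
                                              NONSYN_CLASSES])
  n <- n_background_per_mutation(plan$rate, length(nonsyn_samples))
  deep <- cohort$rna_depth >= plan$min_bg_depth
  syn_pool <- cohort$var_class == "synonymous" & deep & !in_gene
  case_samples <- sort(unique(cohort$sample_id[case_idx]))
  used <- logical(nrow(cohort))
  rows <- integer(0)
  tiers <- character(0)
  total_quota <- 0L
  incomplete <- FALSE
  for (s in case_samples) {
    quota <- n * sum(cohort$sample_id[case_idx] == s)
    total_quota <- total_quota + quota
    pools <- list(
      i_same_sample = which(syn_pool & cohort$sample_id == s),
      ii_mutated_samples = which(syn_pool &
                                   cohort$sample_id %in% nonsyn_samples &
                                   cohort$sample_id != s),
      iii_cohort = which(syn_pool &
                           !cohort$sample_id %in% c(nonsyn_samples, s)))
    if (isTRUE(plan$include_gene_syn))
      pools$vi_gene_syn <- which(in_gene & deep &
                                   cohort$var_class == "synonymous")
    pools$iv_same_class_same_sample <-
      which(!in_gene & deep & cohort$sample_id == s &
              cohort$var_class %in% classes)
    for (tier in names(pools)) {
      if (quota <= 0) break
      avail <- pools[[tier]][!used[pools[[tier]]]]
      if (!length(avail)) next
      take <- min(quota, length(avail))
      pick <- avail[sample.int(length(avail), take)]
      used[pick] <- TRUE
      rows <- c(rows, pick)
      tiers <- c(tiers, rep(tier, take))
      quota <- quota - take
    }
    if (quota > 0) incomplete <- TRUE
  }
  if (!length(rows))
    stop(structure(class = c("rv_no_background", "error", "condition"),
                   list(message = paste0("no background mutations available",
                                         " for gene ", gene),
                        call = sys.call())))
  structure(list(mutations = as.data.frame(cohort)[rows, , drop = FALSE],
                 tier = tiers, target_n = total_quota,
                 n_per_mutation = n, incomplete = incomplete),
            class = "background_draw")
}
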