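#' RNA variant allele frequency
#'
#' The RNA VAF of a mutation is the number of non-duplicated RNA-seq reads
#' supporting the alternate allele divided by the total non-duplicated
#' reads covering the position. Positions with zero RNA coverage are given
#' a VAF of 0 (they later enter the model with the minimal depth weight).
#'
#' @param rna_alt,rna_ref non-negative read counts on the alternate and
#'   reference allele.
#' @return Numeric vector of VAFs in `[0, 1]`.
#' @export
compute_rna_vaf <- function(rna_alt, rna_ref) {
  if (any(rna_alt < 0, na.rm = TRUE) || any(rna_ref < 0, na.rm = TRUE))
    stop("negative read counts")
  depth <- rna_alt + rna_ref
  ifelse(depth > 0, rna_alt / depth, 0)
}

#' Classify the expression status of a mutated position
#'
#' A mutation is `expressed` when two or more non-duplicated reads support
#' the mutated allele; `not_expressed` when fewer than two reads map to
#' either allele; otherwise only the wild-type allele is seen (`wt_only`).
#'
#' @inheritParams compute_rna_vaf
#' @return Character vector with levels `expressed`, `wt_only`,
#'   `not_expressed`.
#' @export
classify_expression <- function(rna_alt, rna_ref) {
  if (any(rna_alt < 0, na.rm = TRUE) || any(rna_ref < 0, na.rm = TRUE))
    stop("negative read counts")
  ifelse(rna_alt >= 2, "expressed",
         ifelse(rna_alt + rna_ref < 2, "not_expressed", "wt_only"))
}

#' Keep synonymous and nonsynonymous single-nucleotide variants
#'
#' Drops records whose class is outside the tested vocabulary
#' (synonymous, missense, nonsense, splice_site, nonstop).
#'
#' @param cohort a `cohort_table`.
#' @return Filtered `cohort_table`.
#' @export
filter_snvs <- function(cohort) {
  keep <- cohort$var_class %in% setdiff(VAR_CLASSES, "other")
  .refresh_cohort(cohort[keep, , drop = FALSE], cohort)
}

#' Remove multinucleotide substitutions reported as adjacent SNVs
#'
#' Within each sample and chromosome, any maximal run of mutated positions
#' at consecutive coordinates (neighbouring positions 1 bp apart) of length
#' two or more is a di-/trinucleotide substitution in disguise and is
#' removed entirely. Idempotent.
#'
#' @param cohort a `cohort_table`.
#' @return Filtered `cohort_table`.
#' @export
remove_multinucleotide <- function(cohort) {
  if (nrow(cohort) == 0) return(cohort)
  grp <- paste(cohort$sample_id, cohort$chrom, sep = "\r")
  drop <- logical(nrow(cohort))
  for (idx in split(seq_len(nrow(cohort)), grp)) {
    up <- sort(unique(cohort$pos[idx]))
    if (length(up) < 2) next
    run <- cumsum(c(TRUE, diff(up) != 1L))
    bad_pos <- up[run %in% as.integer(names(which(table(run) >= 2)))]
    if (length(bad_pos)) drop[idx[cohort$pos[idx] %in% bad_pos]] <- TRUE
  }
  .refresh_cohort(cohort[!drop, , drop = FALSE], cohort)
}

#' Cap the number of mutations per gene per sample
#'
#' When a sample carries more than `cap` mutations in one gene, the `cap`
#' deepest (by RNA depth, ties broken by ascending position) are kept, so
#' the result is deterministic.
#'
#' @param cohort a `cohort_table`.
#' @param cap maximum mutations per (sample, gene); default 3.
#' @return Filtered `cohort_table`.
#' @export
cap_mutations_per_gene_sample <- function(cohort, cap = 3L) {
  stopifnot(cap >= 1)
  if (nrow(cohort) == 0) return(cohort)
  depth <- cohort$rna_alt + cohort$rna_ref
  o <- order(cohort$sample_id, cohort$gene, -depth, cohort$pos)
  grp <- paste(cohort$sample_id, cohort$gene, sep = "\r")[o]
  rank_in_grp <- stats::ave(seq_along(o), grp, FUN = seq_along)
  keep_rows <- sort(o[rank_in_grp <= cap])
  .refresh_cohort(cohort[keep_rows, , drop = FALSE], cohort)
}

#' Compute RNA VAFs, depth weights and expression classes
#'
#' Adds per-mutation columns to the cohort: `rna_depth`, `rna_vaf`,
#' `expression_class`, `zero_depth` and `weight`. The weight is
#' `log2(capped_depth + 1) / max(log2(capped_depth + 1))`, where depths are
#' capped at the cohort's 90th percentile (type-7 quantile) to avoid
#' domination by extremely highly expressed genes. Zero-coverage positions
#' receive the weight of a depth-1 position so they still contribute to the
#' model fit.
#'
#' @param cohort a `cohort_table` (after all mutation-level filters).
#' @param depth_cap_quantile percentile at which RNA depths are capped
#'   (default 0.9).
#' @return The cohort with weight columns added.
#' @export
compute_weights <- function(cohort, depth_cap_quantile = 0.9) {
  if (nrow(cohort) == 0) stop("empty cohort")
  depth <- cohort$rna_alt + cohort$rna_ref
  if (all(depth == 0)) stop("all RNA depths are zero; weights undefined")
  p90 <- stats::quantile(depth, depth_cap_quantile, type = 7, names = FALSE)
  capped <- pmin(depth, p90)
  # a zero-coverage position is weighted like one with a single read
  eff <- ifelse(depth == 0, min(1, p90), capped)
  max_log <- max(log2(capped + 1))
  cohort$rna_depth <- depth
  cohort$rna_vaf <- compute_rna_vaf(cohort$rna_alt, cohort$rna_ref)
  cohort$expression_class <- classify_expression(cohort$rna_alt,
                                                 cohort$rna_ref)
  cohort$zero_depth <- depth == 0
  cohort$weight <- log2(eff + 1) / max_log
  attr(cohort, "depth_cap") <- p90
  cohort
}

#' Genes with enough adequately covered nonsynonymous mutations to test
#'
#' A gene is testable within a cancer type when it carries at least
#' `min_nonsyn` nonsynonymous mutations each covered by at least
#' `min_depth` non-duplicated RNA reads.
#'
#' @param cohort a weighted `cohort_table` (see [compute_weights()]).
#' @param min_nonsyn minimum qualifying nonsynonymous mutations (default 2).
#' @param min_depth minimum RNA depth per qualifying mutation (default 8).
#' @return Sorted character vector of testable gene symbols.
#' @export
select_testable_genes <- function(cohort, min_nonsyn = 2L, min_depth = 8L) {
  ok <- cohort$var_class %in% NONSYN_CLASSES &
    (cohort$rna_alt + cohort$rna_ref) >= min_depth
  if (!any(ok)) return(character(0))
  counts <- table(cohort$gene[ok])
  sort(names(counts)[counts >= min_nonsyn])
}

#' Run the mutation-level preprocessing pipeline
#'
#' Applies, in fixed order: SNV class filtering, multinucleotide-run
#' removal, the per-gene/per-sample mutation cap, and weight computation
#' (weights are computed on the final retained set).
#'
#' @param cohort a raw `cohort_table`.
#' @param cap per-(sample, gene) mutation cap (default 3).
#' @param depth_cap_quantile see [compute_weights()].
#' @return A weighted `cohort_table`.
#' @export
preprocess_cohort <- function(cohort, cap = 3L, depth_cap_quantile = 0.9) {
  cohort <- filter_snvs(cohort)
  cohort <- remove_multinucleotide(cohort)
  cohort <- cap_mutations_per_gene_sample(cohort, cap = cap)
  compute_weights(cohort, depth_cap_quantile = depth_cap_quantile)
}
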