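#' Rank-weighted CGC enrichment score
#'
#' `E(R) = sum_{i=1}^{N} P_i / log(i + 1)`, where `P_i` is the proportion
#' of the `i` most significant genes that are in the Cancer Gene Census.
#' Rewards tools that place known cancer genes at the top of their
#' ranking. When fewer than `N` genes were tested, `N` is the list length.
#'
#' @param is_cgc logical vector, ordered by ascending p value (most
#'   significant first): is each ranked gene a CGC gene?
#' @param N number of top ranks considered (e.g. 250 pan-cancer, 40 per
#'   cancer type).
#' @param log_base base of the logarithm (default natural).
#' @return The CGC score.
#' @export
cgc_score <- function(is_cgc, N = 250L, log_base = exp(1)) {
  if (!length(is_cgc)) stop("empty ranked gene list")
  stopifnot(N >= 1)
  N <- min(N, length(is_cgc))
  i <- seq_len(N)
  Pi <- cumsum(as.logical(is_cgc[i])) / i
  sum(Pi / log(i + 1, base = log_base))
}

#' Fisher's exact test on a 2x2 table of counts
#'
#' Conditional maximum-likelihood odds ratio and two-sided exact p value
#' (probability-mass rule: sum of hypergeometric probabilities no larger
#' than the observed table's).
#'
#' @param a,b,c,d cell counts, rows = groups, columns = outcome
#'   (`a`/`b` top row, `c`/`d` bottom row).
#' @param alternative passed to [stats::fisher.test()].
#' @return List: `odds_ratio`, `p_value`, `conf_int`.
#' @export
fisher_2x2 <- function(a, b, c, d, alternative = "two.sided") {
  counts <- c(a, b, c, d)
  if (any(counts < 0) || any(counts != round(counts)))
    stop("counts must be non-negative integers")
  m <- matrix(counts, nrow = 2, byrow = TRUE)
  if (any(rowSums(m) == 0) || any(colSums(m) == 0))
    stop("degenerate table: zero margin")
  ft <- stats::fisher.test(m, alternative = alternative)
  list(odds_ratio = unname(ft$estimate), p_value = ft$p.value,
       conf_int = unname(ft$conf.int))
}

#' Odds ratio for mutation expression relative to the reference stratum
#'
#' Builds the 2x2 table of expressed versus non-expressed mutations (a
#' mutation is expressed when two or more RNA reads support the mutated
#' allele; wild-type-only positions count as non-expressed) for a target
#' stratum (variant class x CGC membership) against the reference stratum
#' of synonymous mutations in non-CGC genes, and estimates the odds ratio
#' with its 95% exact confidence interval.
#'
#' @param cohort a `cohort_table`.
#' @param class target variant class (e.g. `"nonsense"`).
#' @param in_cgc logical: target stratum inside the CGC list?
#' @param annotation a `gene_annotation`.
#' @return List: `odds_ratio`, `conf_int`, `p_value`, `table`; all-`NA`
#'   with a warning when a stratum is empty.
#' @export
expression_odds_ratio <- function(cohort, class, in_cgc, annotation) {
  cgc <- cohort$gene %in% annotation$cgc_genes
  expressed <- classify_expression(cohort$rna_alt, cohort$rna_ref) ==
    "expressed"
  target <- cohort$var_class == class & cgc == in_cgc
  ref <- cohort$var_class == "synonymous" & !cgc
  if (!any(target) || !any(ref)) {
    warning("empty stratum; odds ratio unavailable")
    return(list(odds_ratio = NA_real_, conf_int = c(NA_real_, NA_real_),
                p_value = NA_real_, table = NULL))
  }
  tab <- matrix(c(sum(target & expressed), sum(target & !expressed),
                  sum(ref & expressed), sum(ref & !expressed)),
                nrow = 2, byrow = TRUE,
                dimnames = list(c("target", "reference"),
                                c("expressed", "not_expressed")))
  ft <- stats::fisher.test(tab)
  list(odds_ratio = unname(ft$estimate), conf_int = unname(ft$conf.int),
       p_value = ft$p.value, table = tab)
}

#' Rank-based AUC of RNA VAF against external driver/passenger labels
#'
#' Mann-Whitney AUC of per-mutation RNA VAFs scoring externally supplied
#' binary labels (e.g. saturation-mutagenesis driver calls), ties
#' mid-ranked. Recurrent mutations (shared `mutation_id`) are collapsed
#' to their median VAF before scoring; their labels must agree.
#'
#' @param vaf per-mutation RNA VAFs.
#' @param labels logical labels (TRUE = positive class).
#' @param mutation_id optional identifier collapsing recurrent mutations.
#' @return The AUC.
#' @export
vaf_label_auc <- function(vaf, labels, mutation_id = NULL) {
  stopifnot(length(vaf) == length(labels))
  labels <- as.logical(labels)
  if (!is.null(mutation_id)) {
    lab_per_id <- tapply(labels, mutation_id, function(x) {
      u <- unique(x)
      if (length(u) > 1) stop("inconsistent labels within a mutation_id")
      u
    })
    vaf <- as.numeric(tapply(vaf, mutation_id, stats::median))
    labels <- as.logical(lab_per_id)
  }
  n1 <- sum(labels)
  n0 <- sum(!labels)
  if (n1 == 0 || n0 == 0) stop("both label classes must be present")
  r <- rank(vaf)  # ties mid-ranked
  (sum(r[labels]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}
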