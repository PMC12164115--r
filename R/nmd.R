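#' Fit decile-based nonsense VAF scaling factors from NMD scores
#'
#' Nonsense-mediated decay suppresses the expression of transcripts with
#' premature termination codons, depressing the RNA VAF of nonsense
#' mutations. An externally supplied per-mutation NMD score (higher = more
#' decay predicted) is binned into deciles among nonsense mutations; the
#' mean RNA VAF within each decile divided by the mean RNA VAF of missense
#' mutations gives a per-decile scaling factor. A global factor (all
#' nonsense / missense) covers mutations without a score, and is the sole
#' factor when fewer than `min_nonsense` scored nonsense mutations exist.
#'
#' Only mutations with positive RNA depth inform the factors.
#'
#' @param cohort a weighted `cohort_table` (see [compute_weights()]).
#' @param min_nonsense minimum scored nonsense mutations for decile fitting
#'   (default 10).
#' @param n_bins number of score bins (default 10 deciles).
#' @return An `nmd_model` list with `decile_edges`, `factor_per_decile`,
#'   `global_factor`, `global_only`.
#' @export
fit_nmd_model <- function(cohort, min_nonsense = 10L, n_bins = 10L) {
  expr <- cohort$rna_depth > 0
  mis <- cohort$var_class == "missense" & expr
  if (!any(mis)) stop("no expressed missense mutations; NMD model undefined")
  mis_mean <- mean(cohort$rna_vaf[mis])
  if (mis_mean <= 0) stop("mean missense RNA VAF is zero; NMD model undefined")
  non <- cohort$var_class == "nonsense" & expr
  global <- if (any(non)) mean(cohort$rna_vaf[non]) / mis_mean else 1
  scored <- non & !is.na(cohort$nmd_score)
  if (sum(scored) < min_nonsense) {
    warning("fewer than ", min_nonsense, " scored nonsense mutations; ",
            "using the global scaling factor only")
    return(structure(list(decile_edges = NULL, factor_per_decile = NULL,
                          global_factor = global, global_only = TRUE),
                     class = "nmd_model"))
  }
  s <- cohort$nmd_score[scored]
  v <- cohort$rna_vaf[scored]
  edges <- stats::quantile(s, probs = seq(0, 1, length.out = n_bins + 1),
                           type = 7, names = FALSE)
  edges <- unique(edges)  # ties collapse bins; factors follow the bins kept
  if (length(edges) < 2) {
    warning("degenerate NMD score distribution; global factor only")
    return(structure(list(decile_edges = NULL, factor_per_decile = NULL,
                          global_factor = global, global_only = TRUE),
                     class = "nmd_model"))
  }
  bin <- cut(s, breaks = edges, include.lowest = TRUE, labels = FALSE)
  k <- length(edges) - 1L
  factors <- rep(global, k)  # empty bins inherit the global factor
  means <- tapply(v, factor(bin, levels = seq_len(k)), mean)
  have <- !is.na(means)
  factors[have] <- means[have] / mis_mean
  structure(list(decile_edges = edges, factor_per_decile = unname(factors),
                 global_factor = global, global_only = FALSE),
            class = "nmd_model")
}

# internal: per-mutation factor lookup
.nmd_factor <- function(model, nmd_score) {
  f <- rep(model$global_factor, length(nmd_score))
  if (!model$global_only) {
    has <- !is.na(nmd_score)
    if (any(has)) {
      bin <- findInterval(nmd_score[has], model$decile_edges,
                          all.inside = TRUE)
      f[has] <- model$factor_per_decile[bin]
    }
  }
  f
}

#' Scale nonsense-mutation RNA VAFs for nonsense-mediated decay
#'
#' Each nonsense mutation's RNA VAF is divided by its decile's scaling
#' factor (restoring the NMD-suppressed VAF upward), with the factor
#' floored at `factor_floor` before division and the result capped at 1.
#' Non-nonsense mutations are returned unchanged. The pre-scaling VAF is
#' kept in `rna_vaf_unscaled`.
#'
#' @param cohort a weighted `cohort_table`.
#' @param model an `nmd_model` from [fit_nmd_model()].
#' @param factor_floor lower bound on the divisor (default 0.05).
#' @return The cohort with `rna_vaf` scaled for nonsense mutations.
#' @export
apply_nmd_scaling <- function(cohort, model, factor_floor = 0.05) {
  stopifnot(inherits(model, "nmd_model"))
  cohort$rna_vaf_unscaled <- cohort$rna_vaf
  idx <- which(cohort$var_class == "nonsense")
  if (length(idx)) {
    f <- pmax(.nmd_factor(model, cohort$nmd_score[idx]), factor_floor)
    cohort$rna_vaf[idx] <- pmin(1, cohort$rna_vaf[idx] / f)
  }
  cohort
}

#' Export / import a fitted NMD model as TSV
#'
#' Plain-text serialisation (item/value rows) for cross-cohort reuse of a
#' fitted model.
#'
#' @param model an `nmd_model`.
#' @param path TSV path.
#' @return `write_nmd_model` returns the path invisibly; `read_nmd_model`
#'   an `nmd_model`.
#' @export
write_nmd_model <- function(model, path) {
  items <- c(if (!model$global_only)
    stats::setNames(model$decile_edges,
                    paste0("edge_", seq_along(model$decile_edges) - 1L)),
    if (!model$global_only)
      stats::setNames(model$factor_per_decile,
                      paste0("factor_", seq_along(model$factor_per_decile))),
    global_factor = model$global_factor)
  utils::write.table(data.frame(item = names(items), value = unname(items)),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_nmd_model
#' @export
read_nmd_model <- function(path) {
  df <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  edges <- df$value[grepl("^edge_", df$item)]
  factors <- df$value[grepl("^factor_", df$item)]
  global <- df$value[df$item == "global_factor"]
  structure(list(decile_edges = if (length(edges)) edges else NULL,
                 factor_per_decile = if (length(factors)) factors else NULL,
                 global_factor = global,
                 global_only = length(edges) == 0),
            class = "nmd_model")
}
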