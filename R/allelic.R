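#' Point estimate of the cancer cell fraction
#'
#' `CCF = VAF / p * ((1 - p) * Ncn + p * Tcn)`, where `p` is tumor purity,
#' `Ncn` the normal and `Tcn` the tumor total copy number at the mutated
#' position. Not capped; callers may cap at 1 for reporting.
#'
#' @param vaf DNA variant allele frequency in `[0, 1]`.
#' @param purity tumor purity in `(0, 1]`.
#' @param ncn normal total copy number (default 2).
#' @param tcn tumor total copy number.
#' @return The CCF estimate.
#' @export
ccf_point_estimate <- function(vaf, purity, ncn = 2, tcn = 2) {
  if (any(purity <= 0)) stop("purity must be positive")
  vaf / purity * ((1 - purity) * ncn + purity * tcn)
}

#' Mutant copy number and mutant copy-number fraction
#'
#' The mutant copy number (number of chromosomal copies bearing the
#' mutation) is `VAF / p * (p * Tcn + Ncn * (1 - p))`; the fraction is the
#' mutant copy number divided by the tumor total copy number, capped at 1.
#'
#' @inheritParams ccf_point_estimate
#' @return `mutant_cn` returns the mutant copy number;
#'   `mutant_cn_fraction` the capped fraction.
#' @export
mutant_cn <- function(vaf, purity, ncn = 2, tcn = 2) {
  if (any(purity <= 0)) stop("purity must be positive")
  vaf / purity * (purity * tcn + ncn * (1 - purity))
}

#' @rdname mutant_cn
#' @export
mutant_cn_fraction <- function(vaf, purity, ncn = 2, tcn = 2) {
  pmin(1, mutant_cn(vaf, purity, ncn, tcn) / tcn)
}

#' CCF credible interval and clonality call
#'
#' Over a CCF grid `0.01, 0.02, ..., 1.00`, the binomial likelihood of the
#' observed DNA alt count given the expected VAF at each grid CCF
#' (`c * purity / ((1 - purity) * ncn + purity * tcn)`) is normalised into
#' a posterior (uniform prior); the central 95% credible interval is read
#' off the posterior CDF. A mutation is clonal when the interval upper
#' bound reaches 1 (the grid maximum).
#'
#' @param dna_alt,dna_depth DNA alt read count and total depth
#'   (`dna_depth >= 1`).
#' @inheritParams ccf_point_estimate
#' @param grid_step CCF grid spacing (default 0.01).
#' @param level credible level (default 0.95).
#' @return List: `ci` (lower, upper) and `clonal`.
#' @export
ccf_interval_clonality <- function(dna_alt, dna_depth, purity, ncn = 2,
                                   tcn = 2, grid_step = 0.01,
                                   level = 0.95) {
  if (dna_depth < 1) stop("dna_depth must be >= 1")
  if (dna_alt > dna_depth) stop("dna_alt exceeds dna_depth")
  if (purity <= 0) stop("purity must be positive")
  grid <- seq(grid_step, 1, by = grid_step)
  ev <- pmin(1, grid * purity / ((1 - purity) * ncn + purity * tcn))
  lik <- stats::dbinom(dna_alt, dna_depth, ev)
  if (sum(lik) == 0) lik <- rep(1, length(grid))
  post <- lik / sum(lik)
  cdf <- cumsum(post)
  alpha <- (1 - level) / 2
  lower <- grid[which(cdf >= alpha)[1]]
  upper <- grid[which(cdf >= 1 - alpha)[1]]
  list(ci = c(lower = lower, upper = upper),
       clonal = upper >= max(grid))
}

#' Upper tail of the beta-binomial distribution
#'
#' `P(X >= m)` for `X ~ BetaBinomial(t, mu, rho)` parameterised by mean
#' `mu` and intraclass correlation (over-dispersion) `rho`, i.e. shapes
#' `alpha = mu (1 - rho) / rho`, `beta = (1 - mu)(1 - rho) / rho`. The
#' tail is computed by direct summation of the pmf on the log scale.
#'
#' @param m observed count (0 <= m <= t).
#' @param t number of trials.
#' @param mu mean success fraction in `(0, 1)`; `0`/`1` degenerate to
#'   exact point masses.
#' @param rho over-dispersion in `(0, 1)` (default 0.05).
#' @return `P(X >= m)`.
#' @export
betabinom_upper_tail <- function(m, t, mu, rho = 0.05) {
  stopifnot(m >= 0, m <= t, rho > 0, rho < 1)
  if (m == 0) return(1)
  if (mu <= 0) return(0)          # X = 0 almost surely
  if (mu >= 1) return(1)          # X = t almost surely, t >= m
  a <- mu * (1 - rho) / rho
  b <- (1 - mu) * (1 - rho) / rho
  k <- m:t
  logpmf <- lchoose(t, k) + lbeta(k + a, t - k + b) - lbeta(a, b)
  min(1, sum(exp(logpmf)))
}

#' Copy-number-aware allele-specific expression test
#'
#' Tests whether the RNA reads supporting the mutated allele exceed the
#' expectation set by the mutation's genomic copy-number state: under 100%
#' tumor-compartment expression the expected allelic fraction is the
#' mutant copy number divided by the total copy number (`CPNratio`). The
#' upper beta-binomial tail `P(X >= rna_alt)` with over-dispersion `rho`
#' gives the ASE p value; p < 0.05 flags copy-number-independent ASE.
#' `CPNratio` is clipped into `[0.001, 0.999]` to avoid degenerate shapes.
#'
#' @param rna_alt,rna_depth RNA alt count and total RNA depth (>= 1).
#' @inheritParams ccf_point_estimate
#' @param rho over-dispersion (default 0.05).
#' @param alpha significance threshold (default 0.05).
#' @return List: `cpn_ratio`, `ase_p`, `ase_flag`.
#' @export
ase_test <- function(rna_alt, rna_depth, vaf, purity, ncn = 2, tcn = 2,
                     rho = 0.05, alpha = 0.05) {
  if (rna_depth < 1) stop("rna_depth must be >= 1")
  cpn <- mutant_cn(vaf, purity, ncn, tcn) / tcn
  cpn <- min(max(cpn, 0.001), 0.999)
  p <- betabinom_upper_tail(rna_alt, rna_depth, cpn, rho)
  list(cpn_ratio = cpn, ase_p = p, ase_flag = p < alpha)
}

#' Per-mutation allelic annotation of a cohort
#'
#' Computes, for every mutation with the required context (purity and
#' copy number), the CCF point estimate and credible interval, clonality,
#' mutant copy number and fraction, the ASE test, and the expression
#' class.
#'
#' @param cohort a `cohort_table` with `purity`, `ncn`, `tcn` filled in.
#' @param rho ASE over-dispersion (default 0.05).
#' @return data.frame with one row per mutation: identifiers plus `ccf`,
#'   `ccf_lower`, `ccf_upper`, `clonal`, `mut_cn`, `mut_cn_fraction`,
#'   `cpn_ratio`, `ase_p`, `ase_flag`, `expression_class`. Mutations
#'   without purity or with zero DNA/RNA depth get `NA` for the
#'   corresponding statistics.
#' @export
annotate_allelic <- function(cohort, rho = 0.05) {
  n <- nrow(cohort)
  out <- data.frame(sample_id = cohort$sample_id, gene = cohort$gene,
                    chrom = cohort$chrom, pos = cohort$pos,
                    var_class = cohort$var_class,
                    ccf = NA_real_, ccf_lower = NA_real_,
                    ccf_upper = NA_real_, clonal = NA,
                    mut_cn = NA_real_, mut_cn_fraction = NA_real_,
                    cpn_ratio = NA_real_, ase_p = NA_real_, ase_flag = NA,
                    stringsAsFactors = FALSE)
  out$expression_class <- classify_expression(cohort$rna_alt,
                                              cohort$rna_ref)
  for (i in seq_len(n)) {
    p <- cohort$purity[i]
    if (is.na(p) || p <= 0) next
    vaf <- cohort$dna_vaf[i]
    ncn <- cohort$ncn[i]
    tcn <- cohort$tcn[i]
    out$ccf[i] <- ccf_point_estimate(vaf, p, ncn, tcn)
    out$mut_cn[i] <- mutant_cn(vaf, p, ncn, tcn)
    out$mut_cn_fraction[i] <- mutant_cn_fraction(vaf, p, ncn, tcn)
    if (cohort$dna_depth[i] >= 1) {
      ci <- ccf_interval_clonality(cohort$dna_alt[i], cohort$dna_depth[i],
                                   p, ncn, tcn)
      out$ccf_lower[i] <- ci$ci[["lower"]]
      out$ccf_upper[i] <- ci$ci[["upper"]]
      out$clonal[i] <- ci$clonal
    }
    rd <- cohort$rna_alt[i] + cohort$rna_ref[i]
    if (rd >= 1) {
      ase <- ase_test(cohort$rna_alt[i], rd, vaf, p, ncn, tcn, rho = rho)
      out$cpn_ratio[i] <- ase$cpn_ratio
      out$ase_p[i] <- ase$ase_p
      out$ase_flag[i] <- ase$ase_flag
    }
  }
  out
}
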