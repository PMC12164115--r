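---
title: "Detecting cancer driver genes from RNA variant allele frequencies"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting cancer driver genes from RNA variant allele frequencies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rnadriver)
```

## The idea

Most driver-gene discovery tools look only at DNA: mutation recurrence,
clustering, or the nonsynonymous/synonymous ratio. `rnadriver` instead asks
whether the somatic mutations of a gene are *expressed more strongly than
expected*. The RNA variant allele frequency (RNA VAF) of a mutation — the
fraction of non-duplicated RNA-seq reads at the mutated position that carry
the mutant allele — integrates several signals that all point the same way
for drivers:

* driver mutations ride clonal sweeps, so they sit in a larger fraction of
  tumor cells (higher cancer cell fraction, CCF);
* mutant alleles of oncogenes are preferentially amplified, and wild-type
  alleles of tumor suppressors are preferentially lost (allelic imbalance);
* allele-specific expression (ASE) can further favor the mutant allele;
* tumor purity and the tumor/normal expression balance act on all mutations
  of a sample alike.

A gene under positive selection should therefore show nonsynonymous RNA
VAFs elevated above a background of passenger-like synonymous mutations
from the same tumors. `rnadriver` formalises that comparison.

## The test

For one cancer-type cohort the pipeline is:

1. **Filter** to synonymous and nonsynonymous SNVs (missense, nonsense,
   splice-site, nonstop). Runs of adjacent mutated positions (1 bp apart,
   within a sample) are di-/trinucleotide substitutions in disguise and are
   removed whole. Each (sample, gene) pair keeps at most `cap = 3`
   mutations (deepest RNA coverage first, position as the tie-break, so
   results are reproducible).
2. **NMD scaling.** Nonsense-mediated decay suppresses nonsense-mutation
   expression and would otherwise mask true signal. Nonsense mutations are
   binned into deciles of an externally supplied NMD score; each decile's
   mean RNA VAF over the missense mean gives a scaling factor, and each
   nonsense VAF is divided by its factor (floored at 0.05, result capped
   at 1). Mutations without a score use the global nonsense/missense
   factor, as does the whole cohort when fewer than 10 scored nonsense
   mutations exist. Division (rather than multiplication) is the direction
   that *restores* suppressed VAFs; the cap keeps the result a fraction.
3. **Weights.** Each mutation gets weight
   `log2(capped_depth + 1) / max(log2(capped_depth + 1))`, with depths
   capped at the cohort's 90th percentile (type-7 quantile, the R
   default). Zero-coverage positions get the weight of a depth-1 position:
   they stay in the model but contribute almost nothing. Weights are
   computed after all mutation-level filters.
4. **Testable genes** need at least 2 nonsynonymous mutations covered by
   at least 8 non-duplicated RNA reads.
5. **Synonymous scaling factor `k`.** Synonymous background VAFs differ
   systematically from the per-gene mean nonsynonymous VAFs of tested
   genes. `k` minimises
   `|k*mean(S) - mean(G)| + |k*median(S) - median(G)|` on the grid
   `0.25–4` (step 0.001), where `S` are depth-eligible synonymous VAFs and
   `G` the per-gene means of tested *non-CGC* genes — known cancer genes
   are excluded so real signal does not inflate the background. `k`
   multiplies synonymous background draws (capped at 1). Same-class
   nonsynonymous fallback draws (tier iv below) are already on the
   nonsynonymous scale and are left unscaled.
6. **Background sampling.** The number of synonymous mutations drawn per
   case mutation is `n = min(round(exp(rate * n_samples)), 2 *
   n_samples)`, with `rate = min(ln(10) / (0.05 * cohort_size), 0.202)`
   chosen so a gene mutated in 5% of the cohort draws 10 per mutation; the
   0.202 cap is the largest 3-decimal rate that still draws a single
   mutation when only two samples are mutated. Draws are without
   replacement, per mutated sample, filling the quota hierarchically:
   (i) synonymous mutations of that sample, (ii) of the other mutated
   samples, (iii) of any cohort sample, optionally (vi) the gene's own
   synonymous mutations, then (iv) same-class nonsynonymous mutations of
   that sample, and finally (v) an incomplete background if all pools are
   exhausted. Tiers i–iii (and iv, for consistency) require 8 or more
   reads. The per-sample matching controls purity and expression-balance
   confounders. Tier vi is tried before tier iv because it supplies
   synonymous mutations, which the hierarchy prefers over nonsynonymous
   stand-ins.
7. **Model.** A weighted linear model `vaf ~ group` compares case and
   background VAFs; the one-sided upper-tail p of the group coefficient is
   kept (selection elevates RNA VAF, so the alternative is
   case > background). Sampling and fitting are bootstrapped 25 times; the
   gene's p value is the geometric mean of the 25, the effect size the
   mean coefficient.
8. **Calls.** Class-specific tests (missense-only, nonsense-only,
   splice-only) run wherever a class has 2 or more mutations, separately
   as well as together; the cancer-type mode (`per_class_min`) reports the
   smallest p of the tests performed, the pan-cancer mode (`combined`) the
   all-nonsynonymous test. Benjamini–Hochberg correction is applied within
   the run and genes with q < 0.25 are flagged as putative drivers.

Taking the minimum over class tests without re-correcting for the 3-way
class multiplicity is deliberately faithful to the published procedure and
is mildly anti-conservative; the simulation calibration below shows the
aggregate behaviour stays inside a reasonable type-I band.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `cap` | 3 | mutations kept per gene per sample |
| `min_nonsyn` | 2 | nonsynonymous mutations needed to test a gene |
| `min_depth` | 8 | RNA reads each qualifying mutation needs |
| `min_bg_depth` | 8 | RNA reads a background mutation needs |
| `depth_cap_quantile` | 0.9 | percentile where RNA depths are capped |
| `B` | 25 | bootstrap replicates |
| `q_thresh` | 0.25 | BH q-value driver threshold |
| `rate_cap` | 0.202 | upper bound on the sampling rate |
| `nmd_factor_floor` | 0.05 | lower bound on NMD divisors |
| `rho` | 0.05 | beta-binomial over-dispersion of the ASE test |

All defaults reproduce the published settings and are exposed both in the
R API and on the command line.

## Allelic statistics

Per mutation, with purity `p`, normal copy number `Ncn` (assumed 2) and
tumor total copy number `Tcn`:

* `CCF = VAF/p * ((1 - p) Ncn + p Tcn)`; its 95% interval comes from a
  binomial likelihood over a CCF grid (0.01–1, step 0.01, uniform prior;
  the upper grid point is exactly 1). A mutation is clonal when the upper
  bound reaches 1. The coarse grid is accurate to about one grid step
  (checked against a 0.001-step refinement).
* mutant copy number `= VAF/p * (p Tcn + Ncn (1 - p))`; the mutant
  copy-number fraction divides by `Tcn` and caps at 1. With `Ncn = 2` the
  CCF and mutant-CN expressions coincide algebraically — a useful internal
  consistency check.
* ASE: under full tumor-compartment expression, the expected mutant-allele
  fraction in RNA is the mutant copy number over the total copy number
  (`CPNratio`, clipped into `[0.001, 0.999]` to avoid degenerate beta
  shapes). `P(X >= rna_alt)` under a beta-binomial with mean `CPNratio`
  and over-dispersion 0.05 flags copy-number-independent ASE at p < 0.05.
  The beta-binomial tail is computed by log-scale pmf summation and is
  verified against direct summation to 1e-10 and against the binomial
  limit as the over-dispersion vanishes.

## What the simulator emulates — and what it does not

`simulation_config()` / `simulate_cohort()` generate cohorts from the same
generative structure the test assumes: per-sample Beta purity; per-gene
Bernoulli mutations with a realistic class mix (30% synonymous, 55%
missense, 10% nonsense, 5% splice); clonal (probability 0.7) or
Uniform(0.2, 0.8) subclonal CCFs; tumor copy number 1–4; binomial DNA
counts at the CCF-implied VAF; negative-binomial RNA depths in per-gene
expression tiers including a zero-expression tier; beta-binomial RNA
counts (over-dispersion 0.05, matching the ASE test's assumption) around
the DNA-implied fraction, NMD-suppressed for nonsense mutations via known
per-decile factors. Driver genes add a configurable elevation `delta` to
the expected RNA VAF of their nonsynonymous mutations and are placed in
expressed tiers — the method cannot, by construction, see a driver whose
transcript is absent, so planting drivers in silent genes would only
measure that truism.

The generator does *not* emulate: mutational-signature sequence context,
gene length or regional mutation-rate variation, sample contamination,
mapping artefacts, or correlated multi-gene selection. Passing calibration
on these cohorts therefore shows the statistical machinery is correct and
calibrated under the model's own assumptions — not that real-data
confounders beyond those assumptions are handled.

Default study conditions are 100 samples and 200 genes per cohort;
calibration experiments pool 2–6 replicates so that null calibration rests
on 200+ tested genes and driver recovery on ~40+ planted-driver tests.
Under these conditions the pipeline shows (seeded runs, recomputed by
`scripts/acceptance.R`): empirical type-I error at p < 0.05 near the
nominal level within [0.02, 0.10]; recovery of 0.3-elevation drivers
mutated in 5 or more samples above 80% at q < 0.25; and an effect-recovery
slope near 1 across planted elevations 0.1/0.2/0.3. Effect recovery is
measured in `combined` mode: the minimum-p extraction of the cancer-type
mode selects among correlated tests and would add selection bias to the
*reported* effect of exactly the kind the calibration is meant to isolate.

## Numerical and design choices

* Rounding in the background count is round-half-to-even (R's `round`);
  exact halves essentially never occur for `exp` values.
* The per-sample background quota multiplies `n` by that sample's count of
  case-class mutations, keeping background size proportional to signal
  size.
* p values are floored at 1e-300 before logs; a gene whose 25 bootstrap
  tests all return the same p (an exhausted background pool) gets exactly
  that p as its geometric mean.
* A residual-free model fit (all case VAFs equal, all background VAFs
  equal) returns p = 0 or 1 by the sign of the contrast, and p = 0.5 with
  effect 0 when every VAF is identical (flagged degenerate).
* Zero-RNA-depth mutations keep VAF 0 — the conservative choice against
  false positives — and the minimal weight, and are flagged.
* The percentile cap for weights is computed after all mutation-level
  filters, on the retained set.
* NMD deciles are defined cohort-wise; scaled VAFs are capped at 1.
* The CGC score `E(R) = sum Pi / log(i + 1)` uses the natural logarithm
  (exposed as an argument).
* Fisher two-sided p values follow the probability-mass rule, R's
  `fisher.test` convention.
* Splice-site mutations use whatever RNA counts are supplied at the
  genomic position; the counting pipeline upstream decides what those
  mean.

## Known limitations

* RNA allele counts are consumed as columns; BAM counting, duplicate
  handling and coordinate lift-over belong to the upstream pipeline.
* The NMD score is an external input; no transcript-structure NMD
  prediction is attempted.
* The ASE construction captures copy-number expectation only; it does not
  deconvolve tumor-versus-normal transcript fractions, so its p values are
  conservative when the tumor transcript fraction exceeds purity.
* Minimum-p class extraction is not re-corrected for class multiplicity
  (see above).
* q values are corrected within one run (one cancer type); cross-cohort
  meta-analysis is out of scope.
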