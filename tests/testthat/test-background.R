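test_that("the sampling rate follows ln(10)/(0.05 n) with a 0.202 cap", {
  expect_equal(compute_sampling_rate(240), log(10) / 12)
  expect_equal(compute_sampling_rate(20), 0.202)  # cap binds
  expect_error(compute_sampling_rate(1), ">= 2")
  # non-increasing in cohort size
  sizes <- c(2, 10, 50, 100, 500, 2000)
  rates <- vapply(sizes, compute_sampling_rate, 0)
  expect_true(all(diff(rates) <= 0))
})

test_that("background count per mutation matches the capped exponential", {
  # a gene mutated in 5% of a 240-sample cohort draws 10 per mutation
  rate <- compute_sampling_rate(240)
  expect_equal(n_background_per_mutation(rate, 12), 10L)
  # at the rate cap, 2 mutated samples draw exactly 1
  expect_equal(n_background_per_mutation(0.202, 2), 1L)
  # brute force: cap of 2*n_samples binds for large n_samples
  oracle <- function(rate, ns) as.integer(min(round(exp(rate * ns)), 2 * ns))
  for (ns in 2:50)
    expect_equal(n_background_per_mutation(0.202, ns), oracle(0.202, ns))
  expect_true(n_background_per_mutation(0.202, 50) == 100L)
})

test_that("the synonymous scaling factor minimises the mean+median objective", {
  # build a cohort where the synonymous VAFs are exactly half the tested
  # genes' mean nonsynonymous VAFs -> closed form k = 2
  g_vafs <- c(0.2, 0.4, 0.6)
  rec <- list()
  for (i in seq_along(g_vafs)) {
    rec[[i]] <- mk_records(2, sample_id = paste0("s", 1:2),
                           gene = paste0("G", i),
                           pos = i * 1000L + c(0L, 10L),
                           rna_alt = as.integer(g_vafs[i] * 20),
                           rna_ref = as.integer(20 - g_vafs[i] * 20))
  }
  syn_vafs <- rep(g_vafs / 2, each = 4)
  rec$syn <- mk_records(length(syn_vafs),
                        sample_id = paste0("t", seq_along(syn_vafs)),
                        gene = "SYN", pos = 90000L + seq_along(syn_vafs) * 10L,
                        var_class = "synonymous",
                        rna_alt = as.integer(syn_vafs * 20),
                        rna_ref = as.integer(20 - syn_vafs * 20))
  co <- compute_weights(cohort_table(do.call(rbind, rec)))
  k <- compute_syn_scaling_factor(co, paste0("G", 1:3), empty_annotation())
  expect_equal(k, 2)
  # identical distributions -> k = 1
  rec$syn$rna_alt <- as.integer(rep(g_vafs, each = 4) * 20)
  rec$syn$rna_ref <- 20L - rec$syn$rna_alt
  co1 <- compute_weights(cohort_table(do.call(rbind, rec)))
  k1 <- compute_syn_scaling_factor(co1, paste0("G", 1:3), empty_annotation())
  expect_equal(k1, 1)
  # optimality: objective at k is no worse than at 1
  obj <- function(k, S, G) abs(k * mean(S) - mean(G)) +
    abs(k * median(S) - median(G))
  S <- co$rna_vaf[co$var_class == "synonymous"]
  G <- tapply(co$rna_vaf[co$var_class != "synonymous"],
              co$gene[co$var_class != "synonymous"], mean)
  expect_lte(obj(k, S, G), obj(1, S, G))
  # all tested genes CGC -> k = 1 with warning
  expect_warning(
    kc <- compute_syn_scaling_factor(co, paste0("G", 1:3),
                                     empty_annotation(paste0("G", 1:3))),
    "non-CGC")
  expect_equal(kc, 1)
})

test_that("synonymous scaling multiplies and caps at 1", {
  expect_equal(apply_syn_scaling(0.3, 1), 0.3)
  expect_equal(apply_syn_scaling(0.6, 2), 1)
  expect_equal(apply_syn_scaling(0.2, 1.5), 0.3)
  expect_error(apply_syn_scaling(0.2, 0), "positive")
})

test_that("when every mutated sample has enough synonymous mutations all draws are tier i", {
  co <- toy_background_cohort(syn_per_sample = 6)
  plan <- sampling_plan(n_cohort(co), rate_cap = 0.202)
  d <- sample_background("CAND", "missense_only", co, plan, seed = 1)
  # 2 mutated samples -> n = 1 per case mutation, 2 case muts per sample
  expect_equal(d$n_per_mutation, 1L)
  expect_equal(d$target_n, 4L)
  expect_equal(nrow(d$mutations), 4)
  expect_true(all(d$tier == "i_same_sample"))
  expect_false(d$incomplete)
  expect_true(all(d$mutations$var_class == "synonymous"))
  expect_true(all(d$mutations$rna_depth >= 8))
})

test_that("tier ii/iii fill the quota when the sample lacks synonymous mutations", {
  # sample s1 has no synonymous mutations at depth >= 8
  co <- toy_background_cohort(syn_per_sample = 3, case_samples = "s1")
  co$rna_alt[co$sample_id == "s1" & co$var_class == "synonymous"] <- 1L
  co$rna_ref[co$sample_id == "s1" & co$var_class == "synonymous"] <- 1L
  co <- compute_weights(co)  # depths changed; re-weight
  plan <- sampling_plan(n_cohort(co), rate_cap = 0.202)
  d <- sample_background("CAND", "missense_only", co, plan, seed = 2)
  # 1 mutated sample -> n = round(exp(0.202)) = 1; 2 case muts -> quota 2
  expect_equal(d$target_n, 2L)
  expect_equal(nrow(d$mutations), 2)
  expect_true(all(d$tier == "iii_cohort"))  # no other mutated samples
  expect_false(d$incomplete)
})

test_that("exhausted pools yield an incomplete draw and never a duplicate", {
  co <- toy_background_cohort(n_samples = 2, syn_per_sample = 1,
                              case_samples = c("s1", "s2"))
  plan <- sampling_plan(n_cohort(co), rate_cap = 0.202)
  d <- sample_background("CAND", "missense_only", co, plan, seed = 3)
  expect_true(d$incomplete)
  expect_lt(nrow(d$mutations), d$target_n)
  key <- paste(d$mutations$sample_id, d$mutations$pos)
  expect_equal(anyDuplicated(key), 0L)
})

test_that("same-class tier iv and the optional gene-synonymous tier engage in order", {
  # no synonymous anywhere; same-sample missense in another gene available
  rec <- rbind(
    mk_records(2, sample_id = "s1", gene = "CAND", pos = c(10L, 30L),
               var_class = "missense", rna_alt = 16L, rna_ref = 4L),
    mk_records(3, sample_id = "s1", gene = "OTHER", pos = c(100L, 200L, 300L),
               var_class = "missense", rna_alt = 6L, rna_ref = 6L),
    mk_records(2, sample_id = "s1", gene = "CAND", pos = c(500L, 600L),
               var_class = "synonymous", rna_alt = 5L, rna_ref = 5L))
  co <- compute_weights(cohort_table(rec))
  plan <- sampling_plan(2, rate_cap = 0.202)  # cohort floor for the rate
  d <- sample_background("CAND", "missense_only", co, plan, seed = 4)
  expect_true(all(d$tier == "iv_same_class_same_sample"))
  expect_true(all(d$mutations$gene != "CAND"))
  # with include_gene_syn the gene's own synonymous mutations come first
  plan2 <- sampling_plan(2, include_gene_syn = TRUE, rate_cap = 0.202)
  d2 <- sample_background("CAND", "missense_only", co, plan2, seed = 4)
  expect_true("vi_gene_syn" %in% d2$tier)
  expect_false("iv_same_class_same_sample" %in% d2$tier)
})

test_that("draws are reproducible under a fixed seed and quota accounting holds", {
  co <- toy_background_cohort(n_samples = 8, syn_per_sample = 5,
                              case_samples = c("s1", "s4", "s7"))
  plan <- sampling_plan(n_cohort(co), rate_cap = 0.202)
  d1 <- sample_background("CAND", "missense_only", co, plan, seed = 42)
  d2 <- sample_background("CAND", "missense_only", co, plan, seed = 42)
  expect_identical(d1$mutations, d2$mutations)
  expect_identical(d1$tier, d2$tier)
  # quota = n per mutation x case mutations (2 per mutated sample)
  expect_equal(d1$target_n, d1$n_per_mutation * 6L)
  if (!d1$incomplete) expect_equal(nrow(d1$mutations), d1$target_n)
})

test_that("a gene with no background at any tier raises a skip condition", {
  rec <- mk_records(2, sample_id = "s1", gene = "CAND", pos = c(10L, 30L),
                    var_class = "missense", rna_alt = 16L, rna_ref = 4L)
  co <- compute_weights(cohort_table(rec))
  plan <- sampling_plan(2, rate_cap = 0.202)
  expect_error(sample_background("CAND", "missense_only", co, plan, seed = 1),
               class = "rv_no_background")
})
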