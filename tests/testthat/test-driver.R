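test_that("the weighted group test matches the pooled-variance t-test at unit weights", {
  case <- c(0.8, 0.6, 0.7)
  bg <- c(0.3, 0.4, 0.2)
  got <- weighted_group_test(case, bg)
  # independent closed-form oracle: one-sided two-sample pooled t-test
  tt <- t.test(case, bg, var.equal = TRUE, alternative = "greater")
  expect_equal(got$p_one_sided, tt$p.value, tolerance = 1e-12)
  expect_equal(got$effect_size, mean(case) - mean(bg), tolerance = 1e-12)
  # several random unit-weight configurations
  set.seed(9)
  for (i in 1:10) {
    cv <- runif(sample(2:6, 1))
    bv <- runif(sample(1:8, 1) + 1)
    g <- weighted_group_test(cv, bv)
    o <- t.test(cv, bv, var.equal = TRUE, alternative = "greater")
    expect_equal(g$p_one_sided, o$p.value, tolerance = 1e-10)
  }
})

test_that("the weighted test is directional and handles degenerate input", {
  # saturated contrast: effect 1, p -> 0
  sat <- weighted_group_test(c(1, 1, 1), c(0, 0, 0))
  expect_equal(sat$effect_size, 1)
  expect_lt(sat$p_one_sided, 1e-6)
  # case below background -> p > 0.5
  low <- weighted_group_test(c(0.1, 0.2), c(0.7, 0.8, 0.9))
  expect_gt(low$p_one_sided, 0.5)
  expect_lt(low$effect_size, 0)
  # all values identical -> flagged degenerate at p = 0.5
  deg <- weighted_group_test(c(0.4, 0.4), c(0.4, 0.4))
  expect_true(deg$degenerate)
  expect_equal(deg$p_one_sided, 0.5)
  expect_equal(deg$effect_size, 0)
  # weights shift the estimate toward the heavier observations
  wt <- weighted_group_test(c(1, 0), c(0.5, 0.5), case_weight = c(10, 0.1))
  expect_gt(wt$effect_size, 0.3)
})

test_that("geometric mean of p values follows exp(mean(log))", {
  expect_equal(geometric_mean_p(rep(0.05, 25)), 0.05)
  expect_equal(geometric_mean_p(c(0.01, 1)), 0.1)
  expect_error(geometric_mean_p(numeric(0)), "empty")
  set.seed(4)
  ps <- runif(25)
  expect_lte(geometric_mean_p(ps), mean(ps))  # AM-GM
  expect_gte(geometric_mean_p(ps), min(ps))
  expect_lte(geometric_mean_p(ps), max(ps))
})

test_that("BH q-values reproduce a hand-executed step-up oracle", {
  expect_equal(bh_qvalues(0.04), 0.04)
  expect_equal(bh_qvalues(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  # independent step-up oracle
  bh_oracle <- function(p) {
    n <- length(p)
    o <- order(p)
    q <- p[o] * n / seq_len(n)
    q <- rev(cummin(rev(q)))
    pmin(1, q)[order(o)]
  }
  set.seed(2)
  for (i in 1:5) {
    ps <- runif(sample(3:40, 1))
    qs <- bh_qvalues(ps)
    expect_equal(qs, bh_oracle(ps), tolerance = 1e-12)
    expect_true(all(qs >= ps & qs <= 1))
    o <- order(ps)
    expect_true(all(diff(qs[o]) >= -1e-12))  # monotone over ranked ps
  }
})

test_that("the bootstrapped gene test is deterministic and aggregates correctly", {
  co <- toy_background_cohort(n_samples = 6, syn_per_sample = 6,
                              case_samples = c("s1", "s3"))
  plan <- sampling_plan(n_cohort(co), rate_cap = 0.202)
  r1 <- bootstrap_gene_test("CAND", "missense_only", co, plan, seed = 5)
  r2 <- bootstrap_gene_test("CAND", "missense_only", co, plan, seed = 5)
  expect_equal(r1$p_geomean, r2$p_geomean)
  expect_equal(r1$effect_size, r2$effect_size)
  ps <- r1$p_boot[[1]]
  expect_length(ps, 25)
  expect_equal(r1$p_geomean, exp(mean(log(ps))))
  # bounds up to round-trip floating error of exp(mean(log(.)))
  expect_gte(r1$p_geomean, min(ps) * (1 - 1e-12))
  expect_lte(r1$p_geomean, max(ps) * (1 + 1e-12))
  # case VAF 0.8 over background 0.3 is strongly significant
  expect_lt(r1$p_geomean, 0.01)
  expect_gt(r1$effect_size, 0.3)
})

test_that("a background pool small enough to be exhausted gives identical bootstrap draws", {
  co <- toy_background_cohort(n_samples = 2, syn_per_sample = 2,
                              case_samples = c("s1", "s2"))
  plan <- sampling_plan(n_cohort(co), rate_cap = 0.202)
  r <- bootstrap_gene_test("CAND", "missense_only", co, plan, seed = 8)
  ps <- r$p_boot[[1]]
  expect_true(all(ps == ps[1]))
  expect_equal(r$p_geomean, ps[1])
})

test_that("class subsets are chosen per the availability rule table", {
  # gene A: 3 missense only; gene B: 1 missense + 1 nonsense
  rec <- rbind(
    mk_records(3, sample_id = c("s1", "s2", "s3"), gene = "A",
               pos = c(10L, 20L, 40L), var_class = "missense",
               rna_alt = 12L, rna_ref = 4L),
    mk_records(2, sample_id = c("s1", "s2"), gene = "B",
               pos = c(100L, 120L), var_class = c("missense", "nonsense"),
               rna_alt = 10L, rna_ref = 6L),
    mk_records(20, sample_id = rep(paste0("s", 1:4), 5),
               gene = paste0("BG", 1:20), pos = 1000L + (1:20) * 100L,
               var_class = "synonymous", rna_alt = 5L, rna_ref = 11L))
  co <- compute_weights(cohort_table(rec))
  res <- suppressWarnings(run_cancer_type(co, empty_annotation(),
                                          mode = "per_class_min", seed = 1))
  expect_setequal(res$gene, c("A", "B"))
  # A has a single represented class: reported as the missense-only test
  expect_equal(res$class_subset[res$gene == "A"], "missense_only")
  # B has no class with >= 2 mutations: falls back to all_nonsyn
  expect_equal(res$class_subset[res$gene == "B"], "all_nonsyn")
  # combined mode always reports all_nonsyn
  resc <- suppressWarnings(run_cancer_type(co, empty_annotation(),
                                           mode = "combined", seed = 1))
  expect_true(all(resc$class_subset == "all_nonsyn"))
  # q-values and driver flags are consistent
  expect_equal(res$driver_flag, res$q_value < 0.25)
  expect_equal(res$q_value, bh_qvalues(res$p_geomean))
})

test_that("effect sign agrees with the weighted mean difference on every draw", {
  co <- toy_background_cohort(n_samples = 6, syn_per_sample = 6,
                              case_samples = c("s2", "s5"), case_vaf = 0.9)
  plan <- sampling_plan(n_cohort(co), rate_cap = 0.202)
  set.seed(31)
  for (i in 1:10) {
    d <- sample_background("CAND", "missense_only", co, plan)
    case <- co$gene == "CAND" & co$var_class == "missense"
    r <- weighted_group_test(co$rna_vaf[case], d$mutations$rna_vaf,
                             co$weight[case], d$mutations$weight)
    wm_case <- weighted.mean(co$rna_vaf[case], co$weight[case])
    wm_bg <- weighted.mean(d$mutations$rna_vaf, d$mutations$weight)
    expect_equal(sign(r$effect_size), sign(wm_case - wm_bg))
  }
})

test_that("the full pipeline is deterministic under a master seed", {
  cfg <- simulation_config(n_samples = 40, n_genes = 60, seed = 5)
  sim <- simulate_cohort(cfg)
  r1 <- suppressWarnings(driver_analysis(sim$cohort, sim$annotation,
                                         seed = 123))
  r2 <- suppressWarnings(driver_analysis(sim$cohort, sim$annotation,
                                         seed = 123))
  expect_equal(r1$p_geomean, r2$p_geomean)
  expect_equal(r1$effect_size, r2$effect_size)
  expect_equal(r1$q_value, r2$q_value)
  m <- attr(r1, "manifest")
  expect_true(is.list(m))
  expect_equal(m$seed, 123)
  expect_true(is.numeric(m$k) && is.numeric(m$rate))
})
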