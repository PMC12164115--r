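# builders for small hand-made cohorts used across tests

mk_records <- function(n, sample_id = paste0("s", seq_len(n)),
                       gene = paste0("g", seq_len(n)),
                       chrom = "chr1", pos = seq_len(n) * 100L,
                       var_class = "missense",
                       rna_alt = 5L, rna_ref = 5L,
                       dna_alt = 20L, dna_depth = 50L,
                       nmd_score = NA_real_, purity = 0.6,
                       ncn = 2L, tcn = 2L) {
  data.frame(sample_id = rep_len(sample_id, n), gene = rep_len(gene, n),
             chrom = rep_len(chrom, n), pos = rep_len(pos, n),
             ref_allele = "C", alt_allele = "T",
             var_class = rep_len(var_class, n),
             dna_alt = rep_len(dna_alt, n),
             dna_depth = rep_len(dna_depth, n),
             dna_vaf = rep_len(dna_alt, n) / rep_len(dna_depth, n),
             rna_alt = rep_len(rna_alt, n), rna_ref = rep_len(rna_ref, n),
             nmd_score = rep_len(nmd_score, n),
             purity = rep_len(purity, n),
             ncn = rep_len(ncn, n), tcn = rep_len(tcn, n),
             stringsAsFactors = FALSE)
}

mk_cohort <- function(...) cohort_table(mk_records(...), cancer_type = "TEST")

# a compact multi-sample cohort with one candidate gene and a synonymous
# background, used by the sampler and driver-test units
toy_background_cohort <- function(n_samples = 5, syn_per_sample = 6,
                                  case_gene = "CAND",
                                  case_samples = c("s1", "s2"),
                                  case_vaf = 0.8, syn_vaf = 0.3,
                                  syn_depth = 20L) {
  rows <- list()
  pos <- 0L
  for (s in paste0("s", seq_len(n_samples))) {
    for (j in seq_len(syn_per_sample)) {
      pos <- pos + 100L
      rows[[length(rows) + 1L]] <- mk_records(
        1, sample_id = s, gene = paste0("BG", pos), pos = pos,
        var_class = "synonymous",
        rna_alt = as.integer(round(syn_vaf * syn_depth)),
        rna_ref = as.integer(syn_depth - round(syn_vaf * syn_depth)))
    }
  }
  for (s in case_samples) {
    for (j in 1:2) {
      pos <- pos + 100L
      rows[[length(rows) + 1L]] <- mk_records(
        1, sample_id = s, gene = case_gene, pos = pos,
        var_class = "missense",
        rna_alt = as.integer(round(case_vaf * 20)),
        rna_ref = as.integer(20 - round(case_vaf * 20)))
    }
  }
  co <- cohort_table(do.call(rbind, rows), cancer_type = "TOY")
  compute_weights(co)
}

empty_annotation <- function(cgc = character(0))
  structure(list(cgc_genes = cgc, oncogenes = character(0),
                 tsgs = character(0)), class = "gene_annotation")
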