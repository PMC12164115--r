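# Column dialect for MC3-style MAF tables with RNA allele counts.
# Every entry is optional; unlisted entries keep the package defaults.
columns:
  sample_id: Tumor_Sample_Barcode
  gene: Hugo_Symbol
  chrom: Chromosome
  pos: Start_Position
  ref_allele: Reference_Allele
  alt_allele: Tumor_Seq_Allele2
  var_class: Variant_Classification
  dna_alt: t_alt_count
  dna_depth: t_depth
  rna_alt: RNA_alt_count
  rna_ref: RNA_ref_count
  nmd_score: NMD_score
  purity: purity
  ncn: ncn
  tcn: tcn
class_map:
  Silent: synonymous
  Missense_Mutation: missense
  Nonsense_Mutation: nonsense
  Splice_Site: splice_site
  Nonstop_Mutation: nonstop
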