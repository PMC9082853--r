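sep: "\t"
columns:
  trait: ProteinID
  variant_chrom: SNP_Chr
  variant_pos: SNP_Pos
  gene: GeneSymbol
  gene_chrom: Gene_Chr
  gene_tss: Gene_TSS
  strength: LogP
  rank: Signal
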