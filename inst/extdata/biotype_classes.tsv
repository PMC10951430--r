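raw_biotype	biotype_class
protein_coding	pcg
lncRNA	lncRNA
lincRNA	lncRNA
antisense	lncRNA
lnc_RNA	lncRNA
miRNA	miRNA
snoRNA	other_small_rna
snRNA	other_small_rna
tRNA	other_small_rna
rRNA	other_small_rna
pcg	pcg
other_small_rna	other_small_rna
other	other
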