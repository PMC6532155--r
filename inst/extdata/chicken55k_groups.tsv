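group	subgroup	n_snps
resequencing	white_feathered	12555
resequencing	yellow_feathered	3940
resequencing	cyan_shank_partridge	2724
gwas	trait_associated	5980
candidate_gene	candidate_gene	7630
rfi	rfi	943
snpdb	snpdb	18412
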