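consequence	n
intergenic variant	16106
intron variant	25275
intron variant & noncoding transcript variant	3981
missense variant	590
missense variant & splice region variant	13
synonymous variant	1601
Splicing	187
start/stop gained/lost/retained	12
3 prime UTR variant	1358
5 prime UTR variant	229
upstream gene variant (1 kb)	871
downstream gene variant (1 kb)	1014
noncoding transcript exon variant	871
unannotated	76
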