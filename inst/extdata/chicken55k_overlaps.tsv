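other_array	n_overlap	n_55k
affy600k	24227	52184
illumina60k	6740	52184
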