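allele_name	snp_position
567-GC1	95
3282-GC1	118
3411-GC1	203
1369-GC1	308
1369-GC2	428
424-GC1	174
1273-GC1	92
1659-GC1	383
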