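chrom	size_mb	n_genes	n_mars
2L	23.0	3048	1067
2R	21.1	3279	1025
3L	24.5	3001	1337
3R	27.9	3759	1437
4	1.3	100	34
X	22.4	2397	2453
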