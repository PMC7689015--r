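key	value
n_inversions	81
genes_in_inversions_z1	22274
tes_in_inversions_z1	9240
c1_z1_pg	0.590
c1_chiifu_pg	0.557
te_pct_z1_ref_genome	31.73
ref_genome_size_mb	529
flow_genome_size_z1_mb	577
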