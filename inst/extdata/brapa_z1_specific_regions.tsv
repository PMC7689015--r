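chromosome	region_label	start	end	length_bp	pct_n	pct_gc	n_genes	cum_gene_len_bp	n_tes	cum_te_len_bp	n_rdna	cum_rdna_len_bp
A01	centromeric	16062102	23330349	7268248	25.51	30.39	230	360211	3207	4608900	47	157414
A05	telomeric	1	6383565	6383565	24.99	35.01	118	709602	2549	4337199	7	22711
A05	centromeric	19127969	33629471	14501503	21.90	36.61	153	947497	6431	11118253	18	57395
A06	pericentromeric	12173306	42412226	30238921	29.87	32.49	419	2408139	12363	19669728	61	193702
A08	centromeric	6540349	8868417	2328069	27.25	29.90	8	1953	580	1554720	0	0
A09	centromeric	21830260	34184774	12354515	54.00	22.20	35	268743	3370	5288282	20	64209
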