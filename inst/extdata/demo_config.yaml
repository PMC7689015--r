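# Fully synthetic demonstration run: a 2 x 120 kb genome pair with one
# planted insertion and one inversion; completes in well under a minute.
outdir: demo_out
simulate:
  seed: 42
  n_chromosomes: 2
  chrom_length: 120000
  n_genes: 6
  te_library:
    - {family: gypsy1, class: LTR_gypsy, consensus_length: 2000, copies_A: 4, copies_B: 6}
    - {family: copia1, class: LTR_copia, consensus_length: 1500, copies_A: 3, copies_B: 3}
  rdna_unit_length: 3000
  rdna_array_copies_A: 2
  rdna_array_copies_B: 2
  planted_insertions:
    - {chrom: 1, position: 60000, length: 20000, w_rdna: 0.3, w_te: 0.3, w_random: 0.4}
  planted_inversions:
    - {chrom: 2, start: 50000, length: 15000}
  snp_divergence: 0.01
  coverage: 8
regions:
  min_region: 15000
  merge_gap: 4000
inversions:
  chain_gap: 10000
landscape:
  window: 20000
phylo:
  family: gypsy1
  bootstrap: 50
  seed: 42
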