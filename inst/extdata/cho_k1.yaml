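# Example CLI config: CHO-K1-like hamster line (defective G1 checkpoint),
# Hprt-style mutation prediction. Gene length and b_max are assay inputs,
# user-supplied; the values here are placeholders, not measurements.
genome_gbp: 4.7
n_chromosomes: 21
g1_checkpoint_competent: false
phase: G1
doses: "0:10:1"
gene_length_bp: 34000
b_max_bp: 5800000
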