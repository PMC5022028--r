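# Example CLI config: repair-competent human fibroblast, G1 exposure.
genome_gbp: 6.1
n_chromosomes: 46
nhej_competent: true
hr_competent: true
g1_checkpoint_competent: true
phase: G1
doses: "0:10:0.5"
plating: delayed
cycling: false
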