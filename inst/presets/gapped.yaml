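# Positive-control regime: deep species splits, tiny within-species
# diversity, no incomplete lineage sorting. Every multi-sample species is
# expected to be monophyletic, the barcode gap clean, and leave-one-out
# identification perfect.
n_sections: 2
species_per_section: 5
sample_counts: [4, 4, 4, 4, 3, 3, 3, 3, 1, 1]
tree_depth: 0.06
min_split_frac: 0.35
theta: 0.0015
ils: 0
kappa: 2
mislabel_rate: 0
locus_missing_rate: 0
outgroup: true
outgroup_depth_mult: 3
loci:
  - name: locusA
    length: 600
    rel_rate: 1.0
    coding: false
    indel_rate: 0
    indel_mean_len: 6
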