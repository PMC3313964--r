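# Low-divergence, ILS-heavy regime of a circumpolar temperate tree genus:
# 56 species in 6 sections, 253 samples (7 singleton species; the rest
# between 2 and 28 samples), two non-coding spacer loci of 698 and 1023
# aligned columns with indels. Calibrated so realized mean interspecific
# and intraspecific K2P rates land near 2.0 and 1.0 per 100 sites, with
# heavy overlap between the two distributions and poor tree-based
# discrimination.
n_sections: 6
species_per_section: [15, 8, 10, 12, 3, 8]
sample_counts: [28, 22, 10, 10, 8, 8, 8, 8, 5, 5, 5, 4, 4, 4, 4, 4,
                4, 4, 4, 4, 4, 4, 4, 4, 4, 4,
                3, 3, 3, 3, 3, 3, 3, 3, 3, 3, 3, 3, 3, 3, 3, 3, 3, 3,
                3, 3, 3, 3, 3,
                1, 1, 1, 1, 1, 1, 1]
tree_depth: 0.010
min_split_frac: 0.02
theta: 0.0038
ils: 0.35
kappa: 2
mislabel_rate: 0.008
locus_missing_rate: 0.08
outgroup: true
outgroup_depth_mult: 3
loci:
  - name: spacer698
    length: 698
    rel_rate: 1.0
    coding: false
    indel_rate: 12
    indel_mean_len: 8
  - name: spacer1023
    length: 1023
    rel_rate: 1.3
    coding: false
    indel_rate: 10
    indel_mean_len: 8
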