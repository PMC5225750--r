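quantity,value
n_mapped_snps,4841
n_linkage_groups,28
total_map_length_cm,1695.46
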