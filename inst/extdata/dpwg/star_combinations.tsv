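# Star alleles defined by the joint presence of component panel variants
# at equal dosage (assumed in cis per DPWG genotyping practice).
gene	components	result
CYP2B6	*9+*4	*6
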