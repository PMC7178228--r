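# CYP2D6 star-allele counts reported for the 547-genome in-house WGS cohort
# (most frequent normal-function and decreased/no-function alleles; 2x547 = 1094 alleles).
allele	count	function_class
*1	351	normal
*2	187	normal
*41	93	decreased
*10	25	decreased
*4	123	no_function
*68+*4	71	no_function
*5	30	no_function
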