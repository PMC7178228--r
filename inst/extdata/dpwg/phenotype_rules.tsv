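# Diplotype-to-phenotype translation rules (DPWG convention).
# kind=class rules match unordered pairs of allele function classes for any gene;
# kind=star rules match explicit unordered star-allele pairs and take precedence.
gene	kind	allele1	allele2	phenotype
*	class	no_function	no_function	PM
*	class	no_function	decreased	IM
*	class	no_function	normal	IM
*	class	no_function	increased	IM
*	class	decreased	decreased	IM
*	class	decreased	normal	NM
*	class	decreased	increased	NM
*	class	normal	normal	NM
*	class	normal	increased	RM
*	class	increased	increased	UM
F5	star	*1	*1	non_carrier
F5	star	*1	Leiden	carrier
F5	star	Leiden	Leiden	carrier
VKORC1	star	*1	*1	normal_sensitivity
VKORC1	star	*1	*2	normal_sensitivity
VKORC1	star	*2	*2	high_sensitivity
HCP5	star	*1	*1	non_carrier
HCP5	star	*1	rs2395029	carrier
HCP5	star	rs2395029	rs2395029	carrier
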