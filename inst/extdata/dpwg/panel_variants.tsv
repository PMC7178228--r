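# DPWG-style pharmacogene panel bundle (curated snapshot, user-extensible)
# schema_version: 1
# bundle_version: dpwg-2019.4-curated
gene	star_label	rsid	chrom	pos_37	pos_38	ref	alt	hgvs_c	function_class	variant_kind
CYP2B6	*4	rs2279343	19	41515263	41009358	A	G	c.785A>G	increased	snv
CYP2B6	*5	rs3211371	19	41522715	41016810	C	T	c.1459C>T	normal	snv
CYP2B6	*9	rs3745274	19	41512841	41006936	G	T	c.516G>T	decreased	snv
CYP2B6	*18	rs28399499	19	41518221	41012316	T	C	c.983T>C	no_function	snv
CYP2C9	*2	rs1799853	10	96702047	94942290	C	T	c.430C>T	decreased	snv
CYP2C9	*3	rs1057910	10	96741053	94981296	A	C	c.1075A>C	no_function	snv
CYP2C9	*5	rs28371686	10	96741058	94981301	C	G	c.1080C>G	no_function	snv
CYP2C9	*6	rs9332131	10	96740980	94981223	AA	A	c.818delA	no_function	indel
CYP2C9	*8	rs7900194	10	96702066	94942309	G	A	c.449G>A	decreased	snv
CYP2C9	*11	rs28371685	10	96740974	94981217	C	T	c.1003C>T	decreased	snv
CYP2C9	*13	rs72558187	10	96698502	94938745	T	C	c.269T>C	no_function	snv
CYP2C19	*2	rs4244285	10	96541616	94781859	G	A	c.681G>A	no_function	snv
CYP2C19	*3	rs4986893	10	96540410	94780653	G	A	c.636G>A	no_function	snv
CYP2C19	*4	rs28399504	10	96522463	94762706	A	G	c.1A>G	no_function	snv
CYP2C19	*5	rs56337013	10	96612495	94852738	C	T	c.1297C>T	no_function	snv
CYP2C19	*6	rs72552267	10	96535210	94775453	G	A	c.395G>A	no_function	snv
CYP2C19	*8	rs41291556	10	96535173	94775416	T	C	c.358T>C	no_function	snv
CYP2C19	*17	rs12248560	10	96521657	94761900	C	T	c.-806C>T	increased	snv
CYP2D6	*3	rs35742686	22	42524243	42128241	AT	A	c.2549delA	no_function	indel
CYP2D6	*4	rs3892097	22	42524947	42128945	C	T	c.506-1G>A	no_function	snv
CYP2D6	*6	rs5030655	22	42525085	42129083	CT	C	c.454delT	no_function	indel
CYP2D6	*8	rs5030865	22	42525182	42129180	C	A	c.505G>T	no_function	snv
CYP2D6	*9	rs5030656	22	42524175	42128173	ACTT	A	c.2615_2617delAAG	decreased	indel
CYP2D6	*10	rs1065852	22	42526694	42130692	G	A	c.100C>T	decreased	snv
CYP2D6	*14	rs5030865	22	42525182	42129180	C	T	c.505G>A	decreased	snv
CYP2D6	*17	rs28371706	22	42525772	42129770	G	A	c.320C>T	decreased	snv
CYP2D6	*41	rs28371725	22	42523805	42127803	C	T	c.985+39G>A	decreased	snv
CYP3A5	*3	rs776746	7	99270539	99672916	T	C	c.219-237A>G	no_function	snv
CYP3A5	*6	rs10264272	7	99262835	99665212	C	T	c.624G>A	no_function	snv
CYP3A5	*7	rs41303343	7	99250393	99652770	T	TT	c.1035dup	no_function	indel
DPYD	*2A	rs3918290	1	97915614	97450058	C	T	c.1905+1G>A	no_function	snv
DPYD	*13	rs55886062	1	97981343	97515787	A	C	c.1679T>G	no_function	snv
DPYD	c.2846A>T	rs67376798	1	97547947	97082391	T	A	c.2846A>T	decreased	snv
DPYD	c.1236G>A	rs56038477	1	98039419	97573863	C	T	c.1236G>A	decreased	snv
F5	Leiden	rs6025	1	169519049	169549811	C	T	c.1601G>A	unknown	snv
SLCO1B1	*5	rs4149056	12	21331549	21178615	T	C	c.521T>C	decreased	snv
SLCO1B1	rs4149015	rs4149015	12	21284647	21131713	G	A	c.-11187G>A	decreased	snv
TPMT	*2	rs1800462	6	18143955	18143724	C	G	c.238G>C	no_function	snv
TPMT	*3B	rs1800460	6	18139228	18138997	C	T	c.460G>A	no_function	snv
TPMT	*3C	rs1142345	6	18130918	18130687	T	C	c.719A>G	no_function	snv
TPMT	*4	rs1800584	6	18129095	18128864	C	T	c.626-1G>A	no_function	snv
UGT1A1	*6	rs4148323	2	234669144	233760498	G	A	c.211G>A	decreased	snv
UGT1A1	*28	rs8175347	2	234668879	233760233	A	ATA	c.-41_-40dup	decreased	indel
UGT1A1	*37	rs8175347	2	234668879	233760233	A	ATATA	c.-43_-40dup	decreased	indel
VKORC1	*2	rs9923231	16	31107689	31096368	C	T	c.174-136C>T	decreased	snv
HCP5	rs2395029	rs2395029	6	31431780	31464003	T	G	n.335T>G	unknown	tag
CYP2D6	*5							whole-gene deletion	no_function	sv_slot
CYP2D6	xN							whole-gene duplication	unknown	sv_slot
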