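# CYP2D6 diplotype calls of three short-read WGS callers on 21 reference samples,
# scored against the GeT-RM 2019 consensus genotypes.
# Notes: hybrid_68 = caller additionally reported a possible *68 hybrid for this sample;
#        dup_unassigned = caller flagged a possible duplication without assigning it;
#        no_phase = caller produced no phased major solution (counted incorrect).
# alternates: manually confirmed allele equivalences, 'a=b' means *a and *b are
#             accepted as the same allele for this sample.
sample	consensus	astrolabe	aldy	stargazer	astrolabe_note	aldy_note	stargazer_note	alternates
HG00436	*2x2/*71	*2/*71	*2x2/*71	*1/*83+*2				
NA07029	*1/*35	*1/*35	*1/*35	*1/*35				
NA18959	*2/*36+*10	*2/*10	*2/*36+*10	*2/*36+*10				
NA19109	*2x2/*29	*2/*29	*2x2/*29	*29/*83+*2				
NA21781	*2x2/*68+*4	*2/*4	*2x2/*68+*4	*4N+*4/*68+*4	dup_unassigned			
NA12878_inhouse	*3/(*68)+*4	*3/*4	*3/*68+*4	*3/*4	hybrid_68			
NA12873	*1/*5	*1/*5	*5/*61	*1/*5		no_phase		
NA18861	*5/*29	*5/*29	*5/*29	*13C/*29				
HG00589	*1/*21	*1/*2	*1/*21	*1/*2				
NA19917	*1/*40	*1/*40	*1/*40	*1/*40				
NA07019	*1/*4	*1/*4	*1/*4	*1/*4				
NA12717	*1/*1	*1/*1	*1/*1	*1/*1				
HG00276	*4/*5	*4/*4	*4/*5	*4/*5				
NA18524	*1/*36x2+*10	*1/*10	*1+*36/*36+*10	*1/*10x3				
NA18540	(*36+)*10/*41	*41/*10	*36+*10/*61+*69	*10x2/*41x2	hybrid_68			
NA12892	*2/*3	*2/*3	*2/*3	*2/*3				
NA07348	*1/*6	*1/*6	*1/*6	*1/*6				
NA18519	*1/*29	*1/*29	*106/*29	*106/*29				1=106
NA18966	*1/*2	*1/*2	*1/*2	*1/*2				
NA18992	*1/*5	*1/*5	*1/*5	*1/*13C				
NA19226	*2/*2x2	*2/*2	*2/*2x2	*2/*83+*2	dup_unassigned			
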