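# Function classes for CYP2D6 star alleles seen in SV-caller diplotypes.
label	function_class
1	normal
2	normal
35	normal
39	normal
9	decreased
10	decreased
17	decreased
29	decreased
41	decreased
14	decreased
3	no_function
4	no_function
5	no_function
6	no_function
7	no_function
8	no_function
36	no_function
40	no_function
68	no_function
21	no_function
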