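# Combined VKORC1/CYP2C9 coumarin (phenprocoumon/warfarin) starting-dose table.
# dose_fraction is percent of the standard starting dose; NA rows fall back to action text.
vkorc1	cyp2c9	dose_fraction	action_text
*1/*1	*1/*1	100	Standard coumarin starting dose.
*2/*2	*2/*2	35	Reduce phenprocoumon/warfarin starting dose to ~35% of standard.
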