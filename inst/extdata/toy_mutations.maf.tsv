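Tumor_Sample_Barcode	Hugo_Symbol	Variant_Classification
SA	DRVA	Nonsense_Mutation
SA	DRVA	Nonsense_Mutation
SA	GA1	Frame_Shift_Ins
SA	GA2	Nonsense_Mutation
SA	GA3	Frame_Shift_Del
SA	GA4	Frame_Shift_Ins
SA	GA5	Nonsense_Mutation
SA	GA6	Frame_Shift_Del
SA	GA7	Frame_Shift_Ins
SA	GA8	Nonsense_Mutation
SA	GS1	Silent
SA	GS2	Silent
SB	GB1	Frame_Shift_Del
SB	GB2	Frame_Shift_Del
SB	GB3	Frame_Shift_Del
SB	GB4	Frame_Shift_Del
SB	GB5	Frame_Shift_Del
SB	GB6	Frame_Shift_Del
SB	GB7	Frame_Shift_Del
SB	GB8	Frame_Shift_Del
SB	GB9	Frame_Shift_Del
SC	DRVB	Frame_Shift_Del
SC	DRVB	Frame_Shift_Del
SC	GC1	Nonsense_Mutation
SC	GC2	Nonsense_Mutation
SC	GC3	Nonsense_Mutation
SC	GM1	Missense_Mutation
SC	GM2	Missense_Mutation
SC	GM3	Missense_Mutation
SC	GM4	Missense_Mutation
SC	GM5	Missense_Mutation
SC	GM6	Missense_Mutation
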