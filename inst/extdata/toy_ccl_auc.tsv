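ccl	cpd1	cpd2	cpd3	cpd4
C1	0.55	0.7	NA	0.62
C2	0.6	0.72	NA	0.64
C3	0.65	0.74	0.5	NA
C4	0.7	0.76	0.52	0.68
C5	0.75	0.78	0.54	0.7
C6	0.4	0.6	0.45	0.5
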