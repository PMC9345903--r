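gene	C1	C2	C3	C4	C5	C6
GX1	3.0	3.5	4.0	4.5	5.0	5.5
GX2	5.0	4.7	4.4	4.1	3.8	3.5
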