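sample	time	event
P01	11	1
P02	10	1
P03	9	1
P04	8	1
P05	7	1
P06	6	1
P07	5	1
P08	4	1
P09	3	1
P10	2	1
P11	1	1
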