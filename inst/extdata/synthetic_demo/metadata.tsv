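sample	treatment	replicate
S01	T1	1
S02	T2	1
S03	T3	1
S04	T1	2
S05	T2	2
S06	T3	2
S07	T1	3
S08	T2	3
S09	T3	3
S10	T1	4
S11	T2	4
S12	T3	4
S13	T1	5
S14	T2	5
S15	T3	5
S16	T1	6
S17	T2	6
S18	T3	6
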