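protein_id	template_id	score
CHD1	PS50013	15.363
CHD1	PS50079	4
CHD1	PS50313	9.155
CHD1	PS50322	9.138
CHD1	PS50324	24.763
CHD1	PS51192	25.932
CHD1	PS51194	19.905
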