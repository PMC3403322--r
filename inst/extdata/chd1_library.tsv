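template_id	source
PS50013	prosite
PS50079	prosite
PS50313	prosite
PS50322	prosite
PS50324	prosite
PS51192	prosite
PS51194	prosite
PS50005	prosite
PS50089	prosite
PS51184	prosite
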