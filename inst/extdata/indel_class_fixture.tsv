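comparison	type	sites	total_bp
kasalath_nipponbare	DEL	5026	13490000
kasalath_nipponbare	INS	2367	1290000
kasalath_9311	DEL	2244	1840000
kasalath_9311	INS	1536	940000
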