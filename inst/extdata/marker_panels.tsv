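platform	gene	probe_id
GPL96	XIST	214218_s_at
GPL96	XIST	221728_x_at
GPL96	KDM5D	206700_s_at
GPL96	RPS4Y1	201909_at
GPL570	XIST	214218_s_at
GPL570	XIST	221728_x_at
GPL570	XIST	224588_at
GPL570	XIST	224589_at
GPL570	XIST	224590_at
GPL570	XIST	227671_at
GPL570	XIST	243712_at
GPL570	KDM5D	206700_s_at
GPL570	RPS4Y1	201909_at
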