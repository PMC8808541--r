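probe_id	gene_id
cg_sig0001	GENEA
cg_sig0002	GENEA
cg_sig0003	GENEB
cg_sig0004	GENEB
cg_sig0004	GENEC
cg_sig0005	GENEC
cg_null0001	GENED
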