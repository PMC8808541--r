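marker_id	coefficient
(Intercept)	12.5
cg_sig0001	40
cg_sig0002	-25
cg_sig0003	60
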