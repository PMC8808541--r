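# Synthetic fixture: probe ids standing in for a cross-reactive blacklist.
cg_null0003
cg_xreact01
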