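# Synthetic fixture: probe ids standing in for a SNP-overlap blacklist.
# Not derived from any published array annotation.
cg_null0001
cg_null0002
cg_badsnp01
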