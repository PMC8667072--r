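# synthetic fixture seed genes (planted-module members)
m003
m004
m008
m009
m010
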