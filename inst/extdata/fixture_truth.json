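{
  "module_members": ["m001", "m002", "m003", "m004", "m005", "m006", "m007", "m008", "m009", "m010"],
  "seeds": ["m003", "m004", "m008", "m009", "m010"],
  "latent_targets": ["m001", "m002", "m005", "m006", "m007"]
}
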