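{
  "kind": "cis_strong",
  "seed": 42,
  "n": 150,
  "truth": "CIS",
  "design": "negbin_sbb",
  "alphaHom": 100,
  "alphaHet": 3,
  "negbinMean": 60,
  "negbinSize": 20
}
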