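# Wallpaper group cm: mirror plus centring (conventional rectangular cell).
name: cm
dimension: 2
bravais: centered-rectangular
multiplicity: 4
generators:
  - "-x, y"
  - "x+1/2, y+1/2"
wyckoff:
  - {label: a, site: "0, y"}
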