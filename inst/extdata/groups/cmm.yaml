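# Wallpaper group c2mm (conventional rectangular cell, centring included).
name: cmm
dimension: 2
bravais: centered-rectangular
multiplicity: 8
generators:
  - "-x, -y"
  - "-x, y"
  - "x+1/2, y+1/2"
wyckoff:
  - {label: a, site: "0, 0"}
  - {label: b, site: "0, 1/2"}
  - {label: c, site: "1/4, 1/4"}
  - {label: d, site: "x, 0"}
  - {label: e, site: "0, y"}
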