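# Wallpaper group p6mm.
name: p6m
dimension: 2
bravais: hexagonal
multiplicity: 12
generators:
  - "x-y, x"
  - "y, x"
wyckoff:
  - {label: a, site: "0, 0"}
  - {label: b, site: "1/3, 2/3"}
  - {label: c, site: "1/2, 0"}
  - {label: d, site: "x, x"}
  - {label: e, site: "x, 0"}
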