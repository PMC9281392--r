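# Wallpaper group p4mm.
name: p4m
dimension: 2
bravais: square
multiplicity: 8
generators:
  - "-y, x"
  - "-x, y"
wyckoff:
  - {label: a, site: "0, 0"}
  - {label: b, site: "1/2, 1/2"}
  - {label: c, site: "1/2, 0"}
  - {label: d, site: "x, x"}
  - {label: e, site: "x, 0"}
  - {label: f, site: "x, 1/2"}
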