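# Wallpaper group p4gm.
name: p4g
dimension: 2
bravais: square
multiplicity: 8
generators:
  - "-y, x"
  - "-x+1/2, y+1/2"
wyckoff:
  - {label: a, site: "0, 0"}
  - {label: b, site: "0, 1/2"}
  - {label: c, site: "x, x+1/2"}
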