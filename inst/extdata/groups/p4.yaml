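# Wallpaper group p4.
name: p4
dimension: 2
bravais: square
multiplicity: 4
generators:
  - "-y, x"
wyckoff:
  - {label: a, site: "0, 0"}
  - {label: b, site: "1/2, 1/2"}
  - {label: c, site: "1/2, 0"}
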