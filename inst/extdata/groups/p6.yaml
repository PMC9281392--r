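# Wallpaper group p6.
name: p6
dimension: 2
bravais: hexagonal
multiplicity: 6
generators:
  - "x-y, x"
wyckoff:
  - {label: a, site: "0, 0"}
  - {label: b, site: "1/3, 2/3"}
  - {label: c, site: "1/2, 0"}
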