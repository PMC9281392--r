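# Wallpaper group p3 (hexagonal axes).
name: p3
dimension: 2
bravais: hexagonal
multiplicity: 3
generators:
  - "-y, x-y"
wyckoff:
  - {label: a, site: "0, 0"}
  - {label: b, site: "1/3, 2/3"}
  - {label: c, site: "2/3, 1/3"}
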