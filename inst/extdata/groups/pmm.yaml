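# Wallpaper group p2mm.
name: pmm
dimension: 2
bravais: rectangular
multiplicity: 4
generators:
  - "-x, -y"
  - "-x, y"
wyckoff:
  - {label: a, site: "0, 0"}
  - {label: b, site: "0, 1/2"}
  - {label: c, site: "1/2, 0"}
  - {label: d, site: "1/2, 1/2"}
  - {label: e, site: "x, 0"}
  - {label: f, site: "x, 1/2"}
  - {label: g, site: "0, y"}
  - {label: h, site: "1/2, y"}
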