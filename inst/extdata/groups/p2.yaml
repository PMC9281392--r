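# Wallpaper group p2: 2-fold rotations.
name: p2
dimension: 2
bravais: oblique
multiplicity: 2
generators:
  - "-x, -y"
wyckoff:
  - {label: a, site: "0, 0"}
  - {label: b, site: "0, 1/2"}
  - {label: c, site: "1/2, 0"}
  - {label: d, site: "1/2, 1/2"}
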