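# Wallpaper group p2mg: 2-fold at origin, mirror at x = 1/4.
name: pmg
dimension: 2
bravais: rectangular
multiplicity: 4
generators:
  - "-x, -y"
  - "-x+1/2, y"
wyckoff:
  - {label: a, site: "0, 0"}
  - {label: b, site: "0, 1/2"}
  - {label: c, site: "1/4, y"}
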