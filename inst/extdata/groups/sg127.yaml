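# Space group 127 (P4/mbm).
name: "127"
dimension: 3
bravais: tetragonal
multiplicity: 16
generators:
  - "-y, x, z"
  - "-x+1/2, y+1/2, -z"
  - "-x, -y, -z"
wyckoff:
  - {label: a, site: "0, 0, 0"}
  - {label: b, site: "0, 0, 1/2"}
  - {label: e, site: "0, 0, z"}
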