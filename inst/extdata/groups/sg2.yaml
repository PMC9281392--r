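# Space group 2 (P-1): inversion.
name: "2"
dimension: 3
bravais: triclinic
multiplicity: 2
generators:
  - "-x, -y, -z"
wyckoff:
  - {label: a, site: "0, 0, 0"}
  - {label: b, site: "0, 0, 1/2"}
  - {label: h, site: "1/2, 1/2, 1/2"}
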