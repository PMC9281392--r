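# Space group 1 (P1): translations only.
name: "1"
dimension: 3
bravais: triclinic
multiplicity: 1
generators: []
wyckoff: []
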