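# Wallpaper group pm: mirror lines at x = 0 and x = 1/2.
name: pm
dimension: 2
bravais: rectangular
multiplicity: 2
generators:
  - "-x, y"
wyckoff:
  - {label: a, site: "0, y"}
  - {label: b, site: "1/2, y"}
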