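# Wallpaper group p1: translations only.
name: p1
dimension: 2
bravais: oblique
multiplicity: 1
generators: []
wyckoff: []
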