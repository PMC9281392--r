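# Wallpaper group pg: glide line along y at x = 0. No special positions.
name: pg
dimension: 2
bravais: rectangular
multiplicity: 2
generators:
  - "-x, y+1/2"
wyckoff: []
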