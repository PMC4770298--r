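# demo layout: one flat-bottomed chamber and one laser-ablated cone pit
features:
  - kind: cylinder_chamber
    center: [150, 150]
    r: 60
    d: 80
  - kind: cone_well
    center: [350, 150]
    r: 50
    d: 60
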