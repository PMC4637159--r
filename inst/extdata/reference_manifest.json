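{
  "seed": 7,
  "ellipsoid_phase": "205966f060545d88edee883d5d2e9e21",
  "cylinder_phase": "2623479108fb1a6eb6db06f9c215816b",
  "network_mask": "e647b0dcd7edef23410d270c9967e19c",
  "network_sites": "1b25ea47d768f9f533ef48670ab78779",
  "curve_ellipsoid": "3fab24217e9450dbde55152ba50a6354",
  "curve_cylinder": "5b3d11580c255097039b584464f32b7d"
}
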