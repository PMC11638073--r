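# Packaged mtSSU assembly pathway configuration.
#
# Transcribed from the reconstructed small-subunit assembly route: 30 single
# species (29 mitoribosomal proteins + the 12S rRNA) and 17 assembly modules,
# each produced by exactly one binding reaction, up to the mature 28S subunit.
# Primed module ids (B5', HB4') denote kinetic variants with identical
# composition. mS37, the last MRP to join according to structural work, was
# not continuously detected and is not part of the modeled species set (it is
# listed in the mtSSU roster file). Module membership for the head modules H2
# and H3 is provisional and editable.
subunit: mtSSU
terminal: mtSSU
species:
  - {id: bS1m,  kind: protein}
  - {id: bS6m,  kind: protein}
  - {id: bS16m, kind: protein}
  - {id: bS18m, kind: protein}
  - {id: bS21m, kind: protein}
  - {id: uS2m,  kind: protein}
  - {id: uS3m,  kind: protein}
  - {id: uS5m,  kind: protein}
  - {id: uS7m,  kind: protein}
  - {id: uS9m,  kind: protein}
  - {id: uS10m, kind: protein}
  - {id: uS11m, kind: protein}
  - {id: uS12m, kind: protein}
  - {id: uS14m, kind: protein}
  - {id: uS15m, kind: protein}
  - {id: uS17m, kind: protein}
  - {id: mS22,  kind: protein}
  - {id: mS23,  kind: protein}
  - {id: mS25,  kind: protein}
  - {id: mS26,  kind: protein}
  - {id: mS27,  kind: protein}
  - {id: mS29,  kind: protein}
  - {id: mS31,  kind: protein}
  - {id: mS33,  kind: protein}
  - {id: mS34,  kind: protein}
  - {id: mS35,  kind: protein}
  - {id: mS38,  kind: protein}
  - {id: mS39,  kind: protein}
  - {id: mS40,  kind: protein}
  - {id: "12S", kind: rna}
modules:
  - {id: B3}
  - {id: B2}
  - {id: B4}
  - {id: B5}
  - {id: "B5'", variant_of: B5}
  - {id: B1}
  - {id: HB1}
  - {id: H1}
  - {id: HB2}
  - {id: HB3}
  - {id: H2}
  - {id: H3}
  - {id: HB4}
  - {id: "HB4'", variant_of: HB4}
  - {id: HB5}
  - {id: HB6}
  - {id: mtSSU}
reactions:
  # body: foot proteins initiate, then B2/B4 join, mS40 + bS16m complete B5
  - {product: B3,     reactants: [mS27, mS34]}
  - {product: B2,     reactants: [mS22, mS25]}
  - {product: B4,     reactants: [uS17m, mS26]}
  - {product: B5,     reactants: [B3, B2, B4, mS40, bS16m]}
  - {product: "B5'",  reactants: [B5]}
  # platform: B1 then uS9m (HB1), head module H1 completes HB2
  - {product: B1,     reactants: [bS1m, uS2m, bS6m, mS23]}
  - {product: HB1,    reactants: [B1, uS9m]}
  - {product: H1,     reactants: [uS10m, mS35]}
  - {product: HB2,    reactants: [HB1, H1]}
  # protein-only head-body scaffold
  - {product: HB3,    reactants: ["B5'", HB2]}
  # rRNA-containing branch
  - {product: H2,     reactants: [mS29, mS31, mS39]}
  - {product: H3,     reactants: [uS3m, uS7m]}
  - {product: HB4,    reactants: [H2, H3, "12S", uS14m, uS15m]}
  - {product: "HB4'", reactants: [HB4]}
  # docking and late compaction
  - {product: HB5,    reactants: [HB3, "HB4'"]}
  - {product: HB6,    reactants: [HB5, uS5m, uS12m, bS18m, mS33, mS38]}
  - {product: mtSSU,  reactants: [HB6, uS11m, bS21m]}
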