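# mtSSU roster: the 30 mitoribosomal proteins of the 28S small subunit plus
# the 12S rRNA. mS37 is listed here but excluded from the kinetic pathway
# configuration (not continuously detected in the gradient data).
subunit: mtSSU
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
  - {id: mS37,  kind: protein}
  - {id: mS38,  kind: protein}
  - {id: mS39,  kind: protein}
  - {id: mS40,  kind: protein}
  - {id: "12S", kind: rna}
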