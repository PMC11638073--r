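# mtLSU roster: the 52 mitoribosomal proteins of the 39S large subunit plus
# the 16S rRNA and the structural tRNA-Val of the central protuberance.
# Module membership (central protuberance CP4/CP5, stalk ST1/ST2, body module
# BM1/BM2, polypeptide exit tunnel PET, membrane anchor A1/A2) is transcribed
# from the reconstructed assembly route; no kinetic reaction topology is
# defined for the large subunit.
subunit: mtLSU
species:
  - {id: uL1m,  kind: protein}
  - {id: uL2m,  kind: protein}
  - {id: uL3m,  kind: protein}
  - {id: uL4m,  kind: protein}
  - {id: uL10m, kind: protein}
  - {id: uL11m, kind: protein}
  - {id: uL13m, kind: protein}
  - {id: uL14m, kind: protein}
  - {id: uL15m, kind: protein}
  - {id: uL16m, kind: protein}
  - {id: uL18m, kind: protein}
  - {id: uL22m, kind: protein}
  - {id: uL23m, kind: protein}
  - {id: uL24m, kind: protein}
  - {id: uL29m, kind: protein}
  - {id: uL30m, kind: protein}
  - {id: bL9m,  kind: protein}
  - {id: bL12m, kind: protein}
  - {id: bL17m, kind: protein}
  - {id: bL19m, kind: protein}
  - {id: bL20m, kind: protein}
  - {id: bL21m, kind: protein}
  - {id: bL27m, kind: protein}
  - {id: bL28m, kind: protein}
  - {id: bL31m, kind: protein}
  - {id: bL32m, kind: protein}
  - {id: bL33m, kind: protein}
  - {id: bL34m, kind: protein}
  - {id: bL35m, kind: protein}
  - {id: bL36m, kind: protein}
  - {id: mL37,  kind: protein}
  - {id: mL38,  kind: protein}
  - {id: mL39,  kind: protein}
  - {id: mL40,  kind: protein}
  - {id: mL41,  kind: protein}
  - {id: mL42,  kind: protein}
  - {id: mL43,  kind: protein}
  - {id: mL44,  kind: protein}
  - {id: mL45,  kind: protein}
  - {id: mL46,  kind: protein}
  - {id: mL48,  kind: protein}
  - {id: mL49,  kind: protein}
  - {id: mL50,  kind: protein}
  - {id: mL51,  kind: protein}
  - {id: mL52,  kind: protein}
  - {id: mL53,  kind: protein}
  - {id: mL54,  kind: protein}
  - {id: mL57,  kind: protein}
  - {id: mL62,  kind: protein}
  - {id: mL63,  kind: protein}
  - {id: mL64,  kind: protein}
  - {id: mL65,  kind: protein}
  - {id: "16S", kind: rna}
  - {id: "tRNA-Val", kind: rna}
modules:
  - {id: CP5, members: [uL18m, mL38]}
  - {id: CP4, members: [mL40, mL46, mL48, mL62, bL31m]}
  - {id: ST2, members: [uL11m, mL54]}
  - {id: ST1, members: [bL12m, uL10m, mL53]}
  - {id: BM1, members: [uL4m, bL20m, bL21m, mL43, mL44, mL50]}
  - {id: BM2, members: [uL4m, bL20m, bL21m, mL43, mL44, mL50, uL15m]}
  - {id: PET, members: [uL23m, uL24m, uL29m, mL37, mL41]}
  - {id: A1,  members: [mL45, bL17m, bL19m, mL39]}
  - {id: A2,  members: [mL45, bL17m, bL19m, mL39, bL32m]}
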