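# Residue-name -> atom-name-prefix -> species mapping used by the structure
# readers. Longest matching prefix wins. Edit or extend to cover other
# naming conventions, then pass this file via the species_map argument.
LIP:
  HD: LIPID_HEAD
  TL: LIPID_TAIL
DDA:
  C: DDA_C
  O: DDA_O
  H: DDA_H
SOL:
  OW: WATER_O
  HW: WATER_H
FLV:
  FL: FLAV
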