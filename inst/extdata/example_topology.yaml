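# Example topology: a skin stack feeding a trunk that splits into two
# nerve branches. Tissue names refer to rows of a tissue property table.
source: src
segments:
  - {tissue: epidermis, from: src, to: n1}
  - {tissue: dermis, from: n1, to: n2}
  - {tissue: subcutaneous_tissue, from: n2, to: n3}
  - {tissue: cervical_vagus_trunk, from: n3, to: fork}
  - {tissue: cardiac_branch, from: fork, to: cardiac}
  - {tissue: hepatic_branch, from: fork, to: hepatic}
terminals:
  cardiac: "T5:B+"
  hepatic: "T6:B+"
anatomy:
  cardiac: Cardiac Plexus
  hepatic: Hepatic Plexus
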