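panel: 5
name: Myeloid-derived suppressor cell phenotypes
markers: [CK, Arg-1, CD11b, CD14, CD33, CD66b, CD68]
phenotypes:
  - rule: CK+
    label: All malignant cells
  - rule: CD68+
    label: All TAMs
  - rule: CD68+Arg-1+
    label: TAM type II
  - rule: CD68+CD11b+
    label: Dendritic macrophages
  - rule: CD11b+CD66b+
    label: Polymorphonuclear leukocyte (PMN)
  - rule: CD11b+Arg-1+CD14+CD33+
    label: Monocytic myeloid-derived suppressor cells (MDSC-M)
  - rule: CD11b+CD66b+CD33+
    label: Granulocytic myeloid-derived suppressor cells (MDSC-PMN)
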