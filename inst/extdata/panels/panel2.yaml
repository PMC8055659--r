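panel: 2
name: T-cell activation and regulation
markers: [CK, CD3, CD8, CD45RO, GZB, FOXP3]
phenotypes:
  - rule: CK+
    label: All malignant cells
  - rule: CD3+
    label: All T lymphocytes
  - rule: CD3+CD8+
    label: Cytotoxic T-cells
  - rule: CD3+CD8+GZB+
    label: Activated cytotoxic T-cells
  - rule: CD3+CD45RO+
    label: Memory T-cells
  - rule: CD3+CD8+CD45RO+
    label: Effector/memory T-cells
  - rule: CD3+FOXP3+CD8-
    label: Regulatory T-cells
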