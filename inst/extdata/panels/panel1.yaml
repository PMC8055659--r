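panel: 1
name: PD-1/PD-L1 axis and T-cells
markers: [CK, CD3, CD8, PD-1, PD-L1, CD68]
phenotypes:
  - rule: CK+
    label: All malignant cells
  - rule: CK+PD-L1+
    label: All malignant cells expressing PD-L1
  - rule: CD3+
    label: All T lymphocytes
  - rule: CD3+CD8+
    label: Cytotoxic T-cells
  - rule: CD3+PD-1+
    label: Antigen experienced T-cells
  - rule: CD3+CD8+PD-1+
    label: Cytotoxic T-cells antigen experienced
  - rule: CD68+
    label: All tumor associated macrophages (TAMs)
  - rule: CD68+PD-L1+
    label: TAM expressing PD-L1
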