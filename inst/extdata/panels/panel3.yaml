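panel: 3
name: Immune checkpoint expression on malignant cells
markers: [CK, CD3, PD-L1, B7-H3, B7-H4, IDO-1, CD68]
phenotypes:
  - rule: CK+
    label: All malignant cells
  - rule: CK+PD-L1+
    label: Malignant cells expressing PD-L1
  - rule: CK+B7-H3+
    label: Malignant cells expressing B7-H3
  - rule: CK+B7-H4+
    label: Malignant cells expressing B7-H4
  - rule: CK+IDO-1+
    label: Malignant cells expressing IDO-1
  - rule: CD3+
    label: All T lymphocytes
  - rule: CD3+PD-L1+
    label: T-cells expressing PD-L1
  - rule: CD3+B7-H3+
    label: T-cells expressing B7-H3
  - rule: CD3+B7-H4+
    label: T-cells expressing B7-H4
  - rule: CD3+IDO-1+
    label: T-cells expressing IDO-1
  - rule: CD68+
    label: All TAMs
  - rule: CD68+PD-L1+
    label: TAM expressing PD-L1
  - rule: CD68+B7-H3+
    label: TAM expressing B7-H3
  - rule: CD68+B7-H4+
    label: TAM expressing B7-H4
  - rule: CD68+IDO-1+
    label: TAM expressing IDO-1
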