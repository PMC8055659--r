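panel: 4
name: Co-stimulatory and inhibitory immune checkpoints on T-cells
markers: [CK, CD3, ICOS, LAG3, OX40, TIM3, VISTA]
phenotypes:
  - rule: CK+
    label: All malignant cells
  - rule: CD3+
    label: All T lymphocytes
  - rule: CD3+VISTA+
    label: T-cells expressing VISTA
  - rule: CD3+ICOS+
    label: T-cells expressing ICOS
  - rule: CD3+LAG3+
    label: T-cells expressing LAG3
  - rule: CD3+OX40+
    label: T-cells expressing OX-40
  - rule: CD3+TIM3+
    label: T-cells expressing TIM3
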