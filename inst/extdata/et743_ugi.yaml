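format_version: '1'
metadata:
  title: Ugi-4CR construct toward ecteinascidin-743
  note: >-
    Three precursor chains of 6, 6 and 2 yield-bearing steps converge in a
    90% Ugi four-component reaction. The chains are weighted by their step
    counts (6, 6, 2). The real precursor count is 17 (three entries are
    double steps), which is the step number used for the efficiency
    denominator.
  n_steps_real: 17
route:
  name: et743-ugi-4cr
  elements:
  - type: convergence
    branches:
    - elements:
      - {type: step, id: a1, yield: 0.89}
      - {type: step, id: a2, yield: 0.9}
      - {type: step, id: a3, yield: 0.85}
      - {type: step, id: a4, yield: 0.91}
      - {type: step, id: a5, yield: 0.97}
      - {type: step, id: a6, yield: 0.89}
    - elements:
      - {type: step, id: b1, yield: 0.79}
      - {type: step, id: b2, yield: 0.94}
      - {type: step, id: b3, yield: 0.72}
      - {type: step, id: b4, yield: 0.98}
      - {type: step, id: b5, yield: 0.93}
      - {type: step, id: b6, yield: 0.99}
    - elements:
      - {type: step, id: c1, yield: 0.95}
      - {type: step, id: c2, yield: 0.87}
  - {type: step, id: ugi, yield: 0.9}
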