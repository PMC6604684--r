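format_version: '1'
metadata:
  title: Convergent case study A-J
  note: >-
    Main reaction set with two convergence points: parallel one-step chains
    A-C (backbone) and V-D meet at C; one-step chain C-E (backbone) and the
    three-step chain X-G meet at E; two trailing steps E-I and I-J.
route:
  name: case-study-A-J
  elements:
  - type: convergence
    branches:
    - elements:
      - {type: step, id: A-C, yield: 0.82}
    - elements:
      - {type: step, id: V-D, yield: 0.65}
  - type: convergence
    branches:
    - elements:
      - {type: step, id: C-E, yield: 0.76}
    - elements:
      - {type: step, id: X-G1, yield: 0.68}
      - {type: step, id: X-G2, yield: 0.73}
      - {type: step, id: X-G3, yield: 0.59}
  - {type: step, id: E-I, yield: 0.9}
  - {type: step, id: I-J, yield: 0.83}
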