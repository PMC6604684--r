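format_version: '1'
metadata:
  title: Decapeptide from two pentapeptide fragments
  note: >-
    Two four-coupling pentapeptide fragments assembled in parallel and
    condensed by one 80% linking step.
route:
  name: decapeptide-two-pentapeptides
  elements:
  - type: convergence
    branches:
    - elements:
      - {type: step, id: p1c1, yield: 0.8}
      - {type: step, id: p1c2, yield: 0.8}
      - {type: step, id: p1c3, yield: 0.8}
      - {type: step, id: p1c4, yield: 0.8}
    - elements:
      - {type: step, id: p2c1, yield: 0.8}
      - {type: step, id: p2c2, yield: 0.8}
      - {type: step, id: p2c3, yield: 0.8}
      - {type: step, id: p2c4, yield: 0.8}
  - {type: step, id: link, yield: 0.8}
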