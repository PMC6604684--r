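format_version: '1'
metadata:
  title: Decapeptide from heptapeptide and tripeptide fragments
  note: >-
    A six-coupling heptapeptide fragment and a two-coupling tripeptide
    fragment condensed by one 80% linking step.
route:
  name: decapeptide-hepta-tri
  elements:
  - type: convergence
    branches:
    - elements:
      - {type: step, id: h1, yield: 0.8}
      - {type: step, id: h2, yield: 0.8}
      - {type: step, id: h3, yield: 0.8}
      - {type: step, id: h4, yield: 0.8}
      - {type: step, id: h5, yield: 0.8}
      - {type: step, id: h6, yield: 0.8}
    - elements:
      - {type: step, id: t1, yield: 0.8}
      - {type: step, id: t2, yield: 0.8}
  - {type: step, id: link, yield: 0.8}
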