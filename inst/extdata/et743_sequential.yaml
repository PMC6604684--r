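format_version: '1'
metadata:
  title: Ecteinascidin-743 construct, fictive sequential variant
  note: >-
    Synthetic comparison route: the same fifteen step yields as the Ugi
    construct run strictly in sequence with no branch averaging. No such
    linear synthesis exists; this is the baseline for quantifying the
    benefit of the convergent architecture.
  synthetic: true
route:
  name: et743-fictive-sequential
  elements:
  - {type: step, id: a1, yield: 0.89}
  - {type: step, id: a2, yield: 0.9}
  - {type: step, id: a3, yield: 0.85}
  - {type: step, id: a4, yield: 0.91}
  - {type: step, id: a5, yield: 0.97}
  - {type: step, id: a6, yield: 0.89}
  - {type: step, id: b1, yield: 0.79}
  - {type: step, id: b2, yield: 0.94}
  - {type: step, id: b3, yield: 0.72}
  - {type: step, id: b4, yield: 0.98}
  - {type: step, id: b5, yield: 0.93}
  - {type: step, id: b6, yield: 0.99}
  - {type: step, id: c1, yield: 0.95}
  - {type: step, id: c2, yield: 0.87}
  - {type: step, id: ugi, yield: 0.9}
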