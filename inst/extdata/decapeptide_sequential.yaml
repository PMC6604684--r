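format_version: '1'
metadata:
  title: Decapeptide, fully sequential assembly
  note: Nine couplings at a uniform 80% yield.
route:
  name: decapeptide-sequential
  elements:
  - {type: step, id: c1, yield: 0.8}
  - {type: step, id: c2, yield: 0.8}
  - {type: step, id: c3, yield: 0.8}
  - {type: step, id: c4, yield: 0.8}
  - {type: step, id: c5, yield: 0.8}
  - {type: step, id: c6, yield: 0.8}
  - {type: step, id: c7, yield: 0.8}
  - {type: step, id: c8, yield: 0.8}
  - {type: step, id: c9, yield: 0.8}
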