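format_version: '1'
metadata:
  title: Tropinone by double Mannich multicomponent reaction
  note: One-pot three-component synthesis, 90% overall yield in one step.
route:
  name: tropinone-robinson-schopf
  elements:
  - {type: step, id: mannich-3cr, yield: 0.9}
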