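format_version: '1'
metadata:
  title: Tropinone, classical linear synthesis
  note: >-
    Represented as a single aggregate step carrying the 0.75% overall
    yield; the individual step yields are not recorded. The real step
    count of 20 (metadata n_steps_real) is the efficiency denominator.
  n_steps_real: 20
route:
  name: tropinone-willstaetter
  elements:
  - {type: step, id: aggregate-20-steps, yield: 0.0075}
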