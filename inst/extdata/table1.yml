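# 2^2 factorial with triplicate centre point: CO2 pressure x cosolvent,
# response = global extract yield (% w/w, g extract / 100 g dried flowers).
# The ternary cosolvent is stored pre-coded as an ordinal factor:
#   -1 = water, 0 = water:ethanol 1:1 v/v, +1 = ethanol.
factors:
- name: P
  unit: bar
  low: 120
  center: 180
  high: 240
- name: M
  unit: coded
  low: -1
  center: 0
  high: 1
responses:
  yield: percent
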