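# 15-run Box-Behnken design (triplicate centre point) in CO2 pressure,
# temperature and mean particle size (Tyler mesh: 42 -> 0.423 mm,
# 60 -> 0.303 mm, 150 -> 0.125 mm). Responses: p-anisic acid selectivity
# (% w/w of crude extract) and global extract yield (% w/w of feed).
# All runs used 4.7% (w/w) ethanol cosolvent.
factors:
- name: P
  unit: bar
  low: 200
  center: 250
  high: 300
- name: T
  unit: degC
  low: 40
  center: 50
  high: 60
- name: G
  unit: mesh
  low: 42
  center: 60
  high: 150
responses:
  selectivity: percent
  yield: percent
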