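# Reproduction config: distal-assay recombination fractions, the minimum
# population rate over the ~110-kb region, and the years-to-generations
# conversion feeding it.
seed: 1
rates:
  counts:
    - label: man53_distal
      k: 158
      "N": 76800
    - label: man20_distal
      k: 42
      "N": 92000
minrate:
  events: 8
  generations: 125
  lineages: 10
  region_length: 110000
tmrca:
  years: 3877
  generation_time: 31
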