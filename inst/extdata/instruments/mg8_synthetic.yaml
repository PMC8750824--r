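# Modified G8: 6 items, total score 0-35, abnormal when the total is >= 6
# (higher scores are worse).
# NOTE: the published modified-G8 item weights come from a regression-based
# re-weighting that is not redistributable here. The item STRUCTURE below
# (six items, score range 0-35, direction, official cutoff) matches the
# published instrument; the level WEIGHTS are synthetic placeholders and
# must be replaced with the published weights before clinical use. Sites
# can drop in their own weights by editing this file or supplying another
# config to load_instrument().
name: mg8
score_min: 0
score_max: 35
abnormal_direction: ">="
cutoff: 6
items:
  - id: weight_loss_3mo
    levels:
      none: 0
      unknown: 2
      kg_1_to_3: 3
      more_than_3kg: 5
  - id: neuropsychological_problems
    levels:
      none: 0
      mild_dementia: 4
      severe_dementia_or_depression: 8
  - id: self_rated_health_vs_peers
    levels:
      better: 0
      as_good: 1
      does_not_know: 3
      not_as_good: 6
  - id: age_class
    levels:
      under_80: 0
      from_80_to_85: 3
      over_85: 6
  - id: more_than_3_medications
    levels:
      "no": 0
      "yes": 4
  - id: mobility
    levels:
      goes_out: 0
      out_of_bed_but_not_outside: 3
      bed_or_chair_bound: 6
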