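# G8 geriatric screening questionnaire: 8 items, total score 0-17,
# abnormal when the total is <= 14 (lower scores are worse).
# Item content transcribed from the original published instrument.
name: g8
score_min: 0
score_max: 17
abnormal_direction: "<="
cutoff: 14
items:
  - id: food_intake_decline_3mo
    levels:
      severe_decrease: 0
      moderate_decrease: 1
      no_decrease: 2
  - id: weight_loss_3mo
    levels:
      more_than_3kg: 0
      unknown: 1
      kg_1_to_3: 2
      none: 3
  - id: mobility
    levels:
      bed_or_chair_bound: 0
      out_of_bed_but_not_outside: 1
      goes_out: 2
  - id: neuropsychological_problems
    levels:
      severe_dementia_or_depression: 0
      mild_dementia: 1
      none: 2
  - id: body_mass_index
    levels:
      below_19: 0
      from_19_below_21: 1
      from_21_below_23: 2
      at_least_23: 3
  - id: more_than_3_medications
    levels:
      "yes": 0
      "no": 1
  - id: self_rated_health_vs_peers
    levels:
      not_as_good: 0
      does_not_know: 0.5
      as_good: 1
      better: 2
  - id: age_class
    levels:
      over_85: 0
      from_80_to_85: 1
      under_80: 2
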