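# Example latent-preference model config (synthetic; not fitted to data).
# Utilities are Plackett-Luce log-worths; demographics are simulation
# dressing; missingness gives the marginal censoring rates.
utilities:
  pain_relief: 3.7
  normal_activities: 1.2
  quality_of_life: 1.0
  sleep: 0.6
  side_effects: 0.5
  mood: 0.3
  less_medication: 0.0
  death: 3.0
  fainting: 2.85
  headache: 2.7
  dizziness: 2.55
  nausea: 2.4
  drowsiness: 2.25
  fatigue: 2.1
  memory_problems: 1.95
  concentration: 1.8
  mood_changes: 1.65
  suicidal_thoughts: 1.5
  weight_gain: 1.35
  appetite_change: 1.2
  dry_mouth: 1.05
  constipation: 0.9
  stomach_problems: 0.75
  skin_problems: 0.6
  vision_problems: 0.45
  tremor: 0.3
  balance_problems: 0.15
  swelling: 0.0
demographics:
  proportion_female: 0.92
  age_median: 52
  age_iqr: 8
  ppi_scale_max: 10
  ppi_median: 4
  ppi_iqr: 3
missingness:
  p_missing_demographics: 0.051
  p_incomplete_benefits: 0.143
  p_incomplete_harms: 0.155
  p_non_tmj: 0.0
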