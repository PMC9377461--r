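[
  {"label": "scenario_1", "atet": 17.8, "prevention_rate": 1.0},
  {"label": "scenario_2", "atet": 17.8, "prevention_rate": 0.25},
  {"label": "scenario_3", "atet": 8.6, "prevention_rate": 1.0},
  {"label": "scenario_4", "atet": 8.6, "prevention_rate": 0.25}
]
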