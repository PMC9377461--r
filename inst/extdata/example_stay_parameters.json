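{
  "description": "Mean length of stay of fallen and unfallen hospitalizations (days) and the approximate daily hospitalization cost in Japan (Yen)",
  "mean_los_fallen": 30.3,
  "mean_los_unfallen": 10.6,
  "daily_cost": 40000
}
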