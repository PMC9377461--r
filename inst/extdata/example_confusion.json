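{
  "description": "Confusion matrix of a fall-prediction model at its Youden cutoff on an evaluation set of 10,386 hospitalizations of inpatients aged 65+ (228 fallen, 10,158 unfallen)",
  "tp": 168,
  "fp": 1638,
  "fn": 60,
  "tn": 8520
}
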