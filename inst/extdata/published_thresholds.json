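[
  {"parameter": "male_age", "direction": "upper", "cutoff": 41, "source_period": "discovery", "status": "validated"},
  {"parameter": "ej_concentration", "direction": "lower", "cutoff": 10.36, "source_period": "discovery", "status": "validated"},
  {"parameter": "ej_total_count", "direction": "lower", "cutoff": 51.79, "source_period": "discovery", "status": "validated"},
  {"parameter": "ej_alkaline_comet", "direction": "upper", "cutoff": 72, "source_period": "discovery", "status": "validated"},
  {"parameter": "su_immotile", "direction": "upper", "cutoff": 45, "source_period": "discovery", "status": "validated"},
  {"parameter": "su_alkaline_comet", "direction": "upper", "cutoff": 59, "source_period": "discovery", "status": "validated"},
  {"parameter": "su_neutral_comet", "direction": "upper", "cutoff": 65, "source_period": "validation", "status": "validated"},
  {"parameter": "bmi", "direction": "upper", "cutoff": 45, "source_period": "discovery", "status": "validated"},
  {"parameter": "infertility_duration", "direction": "upper", "cutoff": 84, "source_period": "validation", "status": "validated"},
  {"parameter": "lh", "direction": "upper", "cutoff": 27.28, "source_period": "discovery", "status": "validated"},
  {"parameter": "antral_follicle_count", "direction": "lower", "cutoff": 3, "source_period": "discovery", "status": "validated"}
]
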