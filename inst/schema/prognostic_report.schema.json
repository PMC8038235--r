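{
  "$schema": "https://json-schema.org/draft/2020-12/schema",
  "title": "prognostic_report",
  "type": "object",
  "required": ["n", "n_pos", "n_neg", "rho", "auc", "threshold",
               "cutoff_lower", "cutoff_upper", "sensitivity", "specificity",
               "ppv", "npv", "lr_pos_exact", "lr_pos_rounded", "lr_neg",
               "pretest_prob", "posttest_population", "posttest_sample"],
  "properties": {
    "n": {"type": "integer"},
    "n_pos": {"type": "integer"},
    "n_neg": {"type": "integer"},
    "rho": {"type": "number", "minimum": -1, "maximum": 1},
    "auc": {"type": "number", "minimum": 0, "maximum": 1},
    "threshold": {"type": "number"},
    "sensitivity": {"type": "number", "minimum": 0, "maximum": 1},
    "specificity": {"type": "number", "minimum": 0, "maximum": 1}
  }
}
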