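{
  "$schema": "https://json-schema.org/draft/2020-12/schema",
  "title": "asymmetry_result",
  "type": "object",
  "required": ["ar2", "ar2_abs", "theta_deg", "n_epochs",
               "eigenvalue_ratio", "degenerate"],
  "properties": {
    "ar2": {"type": "number", "minimum": -100, "maximum": 100},
    "ar2_abs": {"type": "number", "minimum": 0, "maximum": 100},
    "theta_deg": {"type": "number", "minimum": 0, "maximum": 90},
    "n_epochs": {"type": "integer", "minimum": 2},
    "eigenvalue_ratio": {"type": ["number", "string"]},
    "degenerate": {"type": "boolean"}
  }
}
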