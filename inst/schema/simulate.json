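{
  "title": "patest simulation sidecar",
  "type": "object",
  "required": ["package", "version", "seed", "command", "n_requested",
               "n", "censor_zero", "model", "data_file"],
  "properties": {
    "package": {"type": "string"},
    "version": {"type": "string"},
    "seed": {"type": "integer"},
    "command": {"type": "string"},
    "n_requested": {"type": "integer"},
    "n": {"type": "integer"},
    "censor_zero": {"type": "boolean"},
    "model": {"type": "object"},
    "data_file": {"type": "string"}
  }
}
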