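{
  "title": "patest fit report",
  "type": "object",
  "required": ["package", "version", "seed", "command", "m", "pa", "n",
               "estimate", "model", "loglik", "n_params", "aic", "bic",
               "converged", "settings"],
  "properties": {
    "package": {"type": "string"},
    "version": {"type": "string"},
    "seed": {"type": "integer"},
    "settings": {"type": "object"},
    "command": {"type": "string"},
    "m": {"type": "integer"},
    "pa": {"type": "boolean"},
    "n": {"type": "integer"},
    "estimate": {"type": "object"},
    "model": {"type": "object"},
    "loglik": {"type": "number"},
    "n_params": {"type": "integer"},
    "aic": {"type": "number"},
    "bic": {"type": "number"},
    "converged": {"type": "boolean"},
    "ci": {"type": "object"}
  }
}
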