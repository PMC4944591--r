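{
  "title": "patest model diagnostic report",
  "type": "object",
  "required": [
    "package",
    "version",
    "command",
    "model",
    "kmax",
    "tail_mass",
    "d",
    "d_censored"
  ],
  "properties": {
    "package": {
      "type": "string"
    },
    "version": {
      "type": "string"
    },
    "command": {
      "type": "string"
    },
    "model": {
      "type": "object"
    },
    "kmax": {
      "type": "integer"
    },
    "tail_mass": {
      "type": "number"
    },
    "d": {
      "type": "number"
    },
    "d_censored": {
      "type": "number"
    },
    "mean_degree": {
      "type": "number"
    },
    "second_moment": {
      "type": "number"
    },
    "divergent_moments": {
      "type": "array"
    },
    "lowest_divergent": {
      "type": "integer"
    }
  }
}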