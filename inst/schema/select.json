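{
  "title": "patest model-selection report",
  "type": "object",
  "required": ["package", "version", "seed", "command", "m_max", "n",
               "table", "settings"],
  "properties": {
    "package": {"type": "string"},
    "version": {"type": "string"},
    "seed": {"type": "integer"},
    "settings": {"type": "object"},
    "command": {"type": "string"},
    "m_max": {"type": "integer"},
    "n": {"type": "integer"},
    "table": {"type": "array"}
  }
}
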