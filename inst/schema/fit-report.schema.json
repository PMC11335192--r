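{
  "$schema": "http://json-schema.org/draft-07/schema#",
  "title": "gatkit fit report",
  "type": "object",
  "required": ["tool", "version", "analysis"],
  "properties": {
    "tool": { "type": "string" },
    "version": { "type": "string" },
    "analysis": { "type": "string" },
    "boltzmann": { "type": "object" },
    "fit_window_s": { "type": "array" },
    "voltage_range_mV": { "type": "array" },
    "excluded": { "type": "object" },
    "seed": { "type": "integer" },
    "config_hash": { "type": "string" }
  }
}
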