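{
  "$schema": "https://json-schema.org/draft/2020-12/schema",
  "title": "microQC training/QC report",
  "type": "object",
  "required": ["report_version", "toolkit", "toolkit_version", "timestamp",
               "parameters", "qc"],
  "properties": {
    "report_version": {"type": "integer"},
    "toolkit": {"const": "microQC"},
    "toolkit_version": {"type": "string"},
    "timestamp": {"type": "string"},
    "parameters": {"type": "object"},
    "qc": {
      "type": "object",
      "additionalProperties": {
        "type": "object",
        "additionalProperties": {
          "type": ["number", "string", "boolean", "integer"]
        }
      }
    },
    "loss": {
      "type": "object",
      "required": ["overfit", "best_epoch", "min_val_loss",
                   "final_val_loss", "rebound_ratio", "delta"]
    }
  }
}
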