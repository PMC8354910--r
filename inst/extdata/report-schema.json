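{
  "title": "restmvpa experiment report",
  "description": "Structural schema for report.json written by write_report(): required per-subject fields and their JSON types, plus the config snapshot.",
  "subject_record": {
    "subject": "integer",
    "seed": "integer",
    "accuracy": "number",
    "n_trials": "integer",
    "sd_rs_raw": "number",
    "sd_rs_corrected": "number",
    "critical_value": "number",
    "empirical_p": "number",
    "significant": "boolean"
  },
  "required_top_level": ["subjects", "config", "timestamp"]
}
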