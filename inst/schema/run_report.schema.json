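{
  "$schema": "http://json-schema.org/draft-07/schema#",
  "title": "plastidscan run report",
  "type": "object",
  "required": ["config", "n_samples", "n_columns", "diversity",
               "site_summary", "n_diagnostic_sites", "candidates",
               "discrimination"],
  "properties": {
    "config": {
      "type": "object",
      "required": ["window", "step", "max_len", "flank_len",
                   "min_diag_per_group", "min_variable", "max_gap_frac",
                   "scan_step", "pi_cap", "top", "min_ir", "max_ir_mismatch",
                   "model", "B", "threshold", "seed"]
    },
    "n_samples": {"type": "integer", "minimum": 2},
    "n_columns": {"type": "integer", "minimum": 1},
    "structure": {
      "type": ["array", "object", "null"],
      "description": "per-genome id, length, gc_percent, lsc, ssc, ir, rotation_offset"
    },
    "diversity": {
      "type": "array",
      "items": {
        "type": "object",
        "required": ["start", "end", "midpoint", "usable_sites", "pi",
                     "truncated"]
      }
    },
    "site_summary": {
      "type": "object",
      "required": ["n_variable", "n_parsimony_informative", "n_singleton",
                   "n_excluded"]
    },
    "n_diagnostic_sites": {"type": "integer", "minimum": 0},
    "candidates": {
      "type": "array",
      "items": {
        "type": "object",
        "required": ["start", "end", "length", "n_variable", "n_pi",
                     "gap_frac", "pi"]
      }
    },
    "discrimination": {
      "type": "object",
      "additionalProperties": {
        "type": "object",
        "required": ["region", "sites", "result"]
      }
    }
  }
}
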