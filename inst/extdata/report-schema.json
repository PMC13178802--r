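{
  "$schema": "https://json-schema.org/draft/2020-12/schema",
  "title": "ecoenz pipeline report",
  "type": "object",
  "required": ["config", "skipped"],
  "properties": {
    "config": {
      "type": "object",
      "required": ["mode", "n_perm", "seed", "k", "vif_threshold", "alpha"],
      "properties": {
        "mode": {"enum": ["per_replicate", "of_means"]},
        "n_perm": {"type": "integer", "minimum": 99},
        "seed": {"type": "integer"},
        "k": {"type": "integer", "minimum": 1},
        "vif_threshold": {"type": "number", "exclusiveMinimum": 1},
        "alpha": {"type": "number", "exclusiveMinimum": 0, "maximum": 1}
      }
    },
    "skipped": {"type": "array", "items": {"type": "string"}},
    "pca": {
      "type": "object",
      "required": ["prop_var"],
      "properties": {
        "prop_var": {"type": "array", "items": {"type": "number"}}
      }
    },
    "component_tests": {"type": "object"},
    "clustering": {
      "type": "object",
      "required": ["cluster", "purity", "sizes"]
    },
    "permanova": {
      "type": "object",
      "required": ["F", "R2", "p_value", "n_perm", "dispersion_p"],
      "properties": {
        "R2": {"type": "number", "minimum": 0, "maximum": 1},
        "p_value": {"type": "number", "exclusiveMinimum": 0, "maximum": 1}
      }
    },
    "vif_screen": {
      "type": "object",
      "required": ["selected", "vifs"]
    },
    "rda": {
      "type": "object",
      "required": ["constrained_prop", "adj_r2", "p_global", "p_terms",
                   "vifs"]
    }
  }
}
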