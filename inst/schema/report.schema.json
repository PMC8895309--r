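{
  "$schema": "http://json-schema.org/draft-07/schema#",
  "title": "tractmaturity analysis report",
  "type": "object",
  "required": ["provenance", "em_age_regressions",
               "metric_age_correlations", "em_plsc", "maturity",
               "excluded_tracts"],
  "properties": {
    "provenance": {
      "type": "object",
      "required": ["package", "version", "seed", "config", "config_hash"],
      "properties": {
        "package": {"type": "string"},
        "version": {"type": "string"},
        "seed": {"type": "integer"},
        "config": {
          "type": "object",
          "required": ["n_perm", "n_boot", "alpha", "kappa", "fdr_family",
                       "age_cutoff", "seed"]
        },
        "config_hash": {"type": "string"}
      }
    },
    "em_age_regressions": {
      "type": "object",
      "required": ["sdfr", "ldfr", "ldcr"]
    },
    "metric_age_correlations": {
      "type": "array",
      "items": {
        "type": "object",
        "required": ["tract", "hemisphere", "metric", "n", "r", "p_raw"]
      }
    },
    "em_plsc": {"type": "object"},
    "maturity": {"type": "object"},
    "excluded_tracts": {"type": "array"},
    "associations": {
      "type": ["array", "null"],
      "items": {
        "type": "object",
        "required": ["tract", "behavior", "panel", "n", "r", "p_raw",
                     "p_fdr", "bf10"]
      }
    },
    "interactions": {"type": ["object", "array", "null"]}
  }
}
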