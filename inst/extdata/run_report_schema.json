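{
  "$schema": "http://json-schema.org/draft-07/schema#",
  "title": "lipidcc run report",
  "type": "object",
  "required": ["counts", "qc"],
  "properties": {
    "counts": {
      "type": "object",
      "required": ["n_samples", "n_features_extracted",
                   "n_features_detected", "n_outliers_removed",
                   "n_samples_analysed"]
    },
    "qc": {
      "type": "object",
      "required": ["qc_dispersion", "outliers", "prop_nonnormal"]
    },
    "association": {"type": ["object", "null"]},
    "selection": {"type": ["object", "null"]},
    "metrics": {"type": ["object", "null"]},
    "external": {"type": ["object", "null"]},
    "trend": {
      "type": ["object", "null"],
      "properties": {
        "direction": {
          "type": "array",
          "items": {"enum": ["decreasing", "increasing", "non-monotone"]}
        }
      }
    }
  }
}
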