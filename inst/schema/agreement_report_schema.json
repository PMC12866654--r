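{
  "$schema": "http://json-schema.org/draft-07/schema#",
  "title": "ichagree agreement report",
  "type": "object",
  "required": ["n_cases", "n_missed", "n_complete", "event_counts",
               "cohort_summary", "agreement", "tests", "icc_abc2",
               "acceptance", "seed"],
  "properties": {
    "n_cases": {"type": "integer"},
    "n_missed": {"type": "integer"},
    "n_complete": {"type": "integer"},
    "event_counts": {
      "type": "object",
      "required": ["missed", "partial", "ivh_included", "distractor_included"]
    },
    "cohort_summary": {"type": "array"},
    "agreement": {
      "type": "array",
      "items": {
        "type": "object",
        "required": ["pair", "mode", "stratifier", "stratum", "estimable"],
        "estimable_required": ["n", "mean_diff", "sd_diff", "loa_low",
                               "loa_high", "tau_raw", "heteroscedastic"]
      }
    },
    "tests": {"type": "object"},
    "icc_abc2": {"type": "object"},
    "acceptance": {"type": "object"},
    "seed": {"type": "integer"}
  }
}
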