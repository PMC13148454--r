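{
  "case_id": "low_risk_controlled_diabetes",
  "factors": ["comorbidity"],
  "applicability_flags": {"tension_free_closure_achievable": true},
  "fct": 1,
  "delta_c": 6000,
  "policy": "midpoint",
  "overrides": {"p1": 0.07, "p2": 0.04}
}
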