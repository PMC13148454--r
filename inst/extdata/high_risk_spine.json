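{
  "case_id": "high_risk_posterior_spine",
  "factors": ["hardware", "perfusion", "soft_tissue", "operative", "comorbidity"],
  "fct": 3,
  "delta_c": 50000,
  "policy": "midpoint",
  "overrides": {"p1": 0.20, "p2": 0.07},
  "documentation": {
    "crs_drivers": true,
    "expected_failure_trajectory": true,
    "reason_routine_closure_inadequate": true,
    "reconstructive_mechanism": true,
    "anticipated_prevented_events": true
  }
}
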