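# fixture cases built in code, mirroring the package's two shipped examples

high_risk_case <- function(delta_c = 50000, ...) {
  cascade_case(
    factors = c("hardware", "perfusion", "soft_tissue", "operative",
                "comorbidity"),
    fct = 3, delta_c = delta_c,
    overrides = list(p1 = 0.20, p2 = 0.07),
    ...
  )
}

low_risk_case <- function(delta_c = 6000, ...) {
  cascade_case(
    factors = "comorbidity", fct = 1, delta_c = delta_c,
    overrides = list(p1 = 0.07, p2 = 0.04),
    ...
  )
}

# randomized-but-valid decision inputs for property tests
random_inputs <- function(n) {
  p1 <- runif(n, 0.02, 1)
  p2 <- runif(n, 0, 1) * p1 * 0.99          # strictly below p1
  data.frame(
    delta_c = runif(n, 0, 300000),
    p1 = p1, p2 = p2,
    c = runif(n, 0, 1500000),
    c0 = runif(n, 0, 100000)
  )
}
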