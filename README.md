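# cascade

Expected-value decision analysis for complex wound reconstruction.

## The problem

In high-risk wound environments (posterior spine surgery, oncologic
resection, trauma reconstruction, diabetic limb salvage), the economic unit
at stake in the index operation is not the price of the procedure performed
but the **total episode expenditure** conditional on the strategy chosen:
wound failure triggers a trajectory of infection, reoperation, prolonged
hospitalization, post-acute care and readmission whose cost dwarfs the index
charge. `cascade` is for reconstructive surgeons, health-economics analysts
and institutional planners who want that trajectory made visible at the
point of decision.

## The model

Two mutually exclusive index strategies are compared: routine closure (S₁)
and definitive reconstruction (S₂). With C₀ the baseline episode cost, P₁
and P₂ the failure probabilities under each strategy, ΔC the incremental
reconstruction cost (facility/operative; physician fees excluded) and C the
expected failure trajectory cost conditional on failure:

    E[Cost | S₁] = C₀ + P₁ · C
    E[Cost | S₂] = C₀ + ΔC + P₂ · C

so reconstruction is favored on expected-value grounds exactly when

    ΔC < (P₁ − P₂) · C = ΔP · C

C₀ cancels from the comparison. Inputs are standardized by an additive
**Clinical Risk Score** (CRS, 0–13 points over eight risk factors) that bands
cases into Low / Moderate / High / Extreme risk tiers indexing published
probability ranges, and by a four-level **Failure Cost Tier** (limited →
catastrophic) indexing episode cost ranges. Around the deterministic rule
the package provides one-way and two-way threshold grids, a seeded Monte
Carlo probabilistic sensitivity analysis, cohort-level avoided-exposure
arithmetic, and a synthetic case generator.

## Worked example

```r
library(cascade)

case <- cascade_case(
  factors = c("hardware", "perfusion", "soft_tissue", "operative", "comorbidity"),
  fct = 3,                    # severe failure trajectory ($400k-$800k)
  delta_c = 50000,
  overrides = list(p1 = 0.20, p2 = 0.07)
)
cascade_decide(case)
```

```
== Wound reconstruction decision analysis ==
CRS 8 (High tier); factors: hardware, perfusion, soft_tissue, operative, comorbidity
P1 = 0.2, P2 = 0.07, dP = 0.13
Failure trajectory cost C = $600,000.00
Threshold dP x C = $78,000.00; incremental cost dC = $50,000.00
Expected episode cost: S1 (closure) $120,000.00  S2 (reconstruction) $92,000.00
Verdict: reconstruction_favored
```

A CRS of 8 places the case in the High tier; at the representative severe
trajectory cost of $600,000 and an absolute risk reduction of 0.13, up to
$78,000 of incremental reconstruction cost is economically justified, so a
$50,000 reconstruction lowers the expected episode cost by $28,000. The
model is bidirectional — a low-risk case (CRS 1, tier-1 costs) yields a
$5,250 threshold and favors routine closure for any realistic ΔC:

```r
cascade_decide(system.file("extdata/low_risk.json", package = "cascade"))
```

Sensitivity and cohort views:

```r
two_way_grid()                     # threshold C x dP over all tiers
run_psa(psa_config(delta_c = 78000, p1 = 0.20, p2 = 0.07,
                   c = c(400000, 800000), n_samples = 10000, seed = 42))
sc <- cohort_scenario(100, c(0.15, 0.25), c(0.05, 0.10), c(400000, 1000000))
avoided_exposure(events_avoided(sc), sc$costs, 100)
```

A shell interface covering `score`, `decide`, `params`, `sensitivity`,
`psa`, `cohort` and `generate` is installed at
`system.file("cli/cascade", package = "cascade")`.

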