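---
title: "Methods: trajectory-based expected-value analysis for wound reconstruction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: trajectory-based expected-value analysis for wound reconstruction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cascade)
```

## The decision model

The package compares two mutually exclusive index strategies for a complex
wound: routine closure (S₁) and definitive reconstruction (S₂). Writing C₀
for the baseline episode cost, P₁ and P₂ for the probability of wound
failure under each strategy, ΔC for the incremental reconstruction cost at
the index operation and C for the expected total episode cost conditional
on failure (the *failure trajectory cost*), the expected total episode
costs are

$$E[\mathrm{Cost} \mid S_1] = C_0 + P_1 C, \qquad
  E[\mathrm{Cost} \mid S_2] = C_0 + \Delta C + P_2 C.$$

Reconstruction is favored exactly when $\Delta C < (P_1 - P_2)\,C = \Delta P \cdot C$.
The model's assumptions are deliberately spare: failure is a Bernoulli event
per case, the trajectory cost does not depend on which strategy failed, and
C₀ is common to both arms so it cancels from the comparison (the verdict
never depends on it; a property test enforces this). Physician professional
fees are excluded structurally — no input field exists for them — because
they would shift both arms proportionally without altering the direction of
the comparison. Intermediate strategies (staged debridement, NPWT bridging,
delayed closure) are not separate strategy objects; they are evaluated by
choosing ΔC, P₂ and C accordingly.

## Risk scoring and applicability

The Clinical Risk Score is an additive 0–13 point score over eight factors:
five wound/reconstruction-specific 2-point factors (perfusion compromise,
hardware present, closure tension, soft tissue destruction, prior failure)
and three contextual 1-point amplifiers (contamination, operative factors,
comorbidity). Scores band into tiers 0–2 Low, 3–5 Moderate, 6–8 High, 9+
Extreme. Two conventions are worth stating explicitly:

* The catalog's points sum to 13 even though the score range is sometimes
  quoted as 0–12; the implementation accepts 13 (the Extreme band is
  open-ended) rather than silently capping.
* Scoring is purely additive; interaction effects among factors are not
  modeled. The catalog is data, not code — point weights can be loaded from
  a config file so re-weighted variants (e.g. regression- or
  Delphi-derived) can be explored without code changes.

The applicability gate flags an analysis as "not applicable" when the CRS
falls in the Low tier or when an explicit exclusion flag is set
(tension-free closure achievable; no contamination/hardware/perfusion
compromise; standard comorbidity burden). The flags are deliberate clinical
judgments recorded in the case file, not the negation of scored factors —
"tension-free closure achievable" is an assessment, not the absence of the
closure-tension point. The gate annotates results; it never blocks
computation, because the model's bidirectionality (favoring closure in
low-risk settings) is itself informative.

## Parameter tables and bound policies

Failure probabilities come from a tier-conditional table of published
ranges; failure trajectory costs from four scenario tiers (limited,
moderate, severe, catastrophic) with representative values $175,000 /
$325,000 / $600,000 / $900,000 at the range midpoints. Ranges resolve to
points under a bound policy: `midpoint` for typical cases, `upper` for
clustered high-risk features, `lower` for borderline presentations, with
explicit overrides taking precedence.

Numerical conventions:

* **Midpoints are exact arithmetic means, never rounded.** Quoted example
  midpoints are sometimes rounded (a Low-tier P₂ of 0.04 versus the
  arithmetic 0.035; a High-tier P₂ of 0.07 versus 0.075); the worked
  examples shipped with the package therefore carry those values as
  explicit overrides, and the default policy documents the divergence
  rather than reproducing the rounding.
* **ΔP is always computed as P₁ − P₂ from the resolved values.** The
  published ΔP ranges are carried as reference columns only, since they are
  not the elementwise differences of the P₁ and P₂ ranges.
* **The catastrophic tier's open upper bound ("$1,000,000+") affects
  display only.** Deterministic arithmetic and default sampling use
  $1,000,000; an explicit larger bound can be passed to explore a longer
  tail.
* **Overrides outside a published range warn, never fail** — actual costs
  vary by year, geography and payer mix — but overrides violating hard
  invariants (probabilities outside [0, 1], P₂ ≥ P₁, negative costs) are
  errors.
* Currency is plain USD numbers computed in double precision; all published
  values are exact at cent precision under float64, and rounding to two
  decimals happens only at display.

The three-way verdict (favored / indeterminate / not favored) is defined on
real-valued equality at the threshold, which is meaningless in floating
point; the indeterminate band therefore has a configurable half-width,
defaulting to `max(1e-9 · threshold, $0.005)` — far below a cent relative
to any realistic threshold. This default is a package choice, made to keep
the three-way rule testable.

## Sensitivity analysis

`two_way_grid()` crosses failure costs with ΔP values; its default axes are
the four representative tier costs × ΔP ∈ {0.05, 0.10, 0.13, 0.20, 0.25},
and each cell equals `decision_threshold()` on the same inputs (a tested
consistency invariant). `directional_robustness()` records the claim that
high/extreme-risk environments keep the threshold above $50,000 whenever
ΔP ≥ 0.10: the claim presumes such cases select severe-or-worse cost
trajectories (the moderate tier gives $32,500 at ΔP = 0.10), so the
assertion is evaluated over cost tiers 3–4 only, and the ambiguity is
documented here rather than papered over.

`run_psa()` is a seeded Monte Carlo propagation of the ranges through the
decision rule. Design choices, each genuinely open and decided as follows:

* **Joint distribution of (P₁, P₂).** No joint law is published. P₁ and P₂
  are sampled independently from their marginal ranges and the ordering
  P₂ < P₁ is enforced by resampling P₂ (up to 1000 rounds), which preserves
  both marginal supports while guaranteeing a positive risk reduction. The
  rejection rate is reported; configurations whose draws can never satisfy
  the ordering (e.g. point masses with P₂ ≥ P₁) error out with that rate.
* **Distributions.** Uniform over the published range is the default — the
  ranges are bounds, not distributions, and uniform adds the least
  structure. A symmetric triangular with mode at the midpoint is offered to
  reflect the "midpoint for typical cases" guidance. Scalars are point
  masses, so a degenerate configuration reproduces the deterministic
  verdict exactly.
* **Outputs.** The headline output is the fraction of draws in which
  reconstruction is favored at the fixed ΔC, with its binomial Monte Carlo
  standard error, plus mean and quantiles of the threshold and of the
  expected-cost difference. These outputs are package plumbing (the
  probabilistic extension is proposed, not specified); they follow the
  conventions of cost-effectiveness acceptability reporting.
* **Reproducibility.** The seed is mandatory; results are bit-identical per
  seed, and the sampler restores the caller's RNG state.

## Cohort modeling

`events_avoided()` converts rate ranges into avoided failure events by
interval arithmetic: the low bound pairs lower baseline with lower
intervention rate, the high bound takes the widest corner pairing (upper
baseline minus lower intervention) — for 100 cases at 15–25% versus 5–10%
this yields the conventional 10–20 fewer events. These are interval bounds,
not confidence intervals. `avoided_exposure()` multiplies event bounds by
cost bounds and normalizes per case; `institutional_exposure()` is the
annual service-line expected value (volume × rate × average cost bound).
`simulate_cohort()` realizes the identities stochastically — Bernoulli
failure per case, uniform cost draw on failure, ΔC added under
reconstruction — and its mean cost difference converges to ΔP·E[C] − ΔC, a
parameter-recovery property tested at `n_reps = 100000` against three Monte
Carlo standard errors.

## Synthetic cases

The generator emulates a clinic's case mix only in the coarsest sense: each
risk factor is an independent Bernoulli with configurable prevalence
(default 0.3, a mix where moderate/high-risk wounds dominate without being
universal), the failure cost tier follows the risk tier (Low→1 … Extreme→4,
mirroring how the worked examples pair risk environment with expected
trajectory), and ΔC is uniform on $20,000–$80,000 — the range over which
the high-risk thresholds of the two-way grid actually bite, and a realistic
span for incremental flap/graft facility costs. An optional exchangeable
Gaussian-copula correlation is available because high-risk factors coexist
in practice; thresholding at the marginal quantile preserves each factor's
prevalence while inflating the variance of the score.

What passing tests on synthetic data do **not** show: that real prevalences,
real cost distributions or real factor dependence look like this. The
generator exists so the pipeline — scoring, resolution, decision, I/O,
CLI — is exercised end-to-end without patient data, and its distributional
sanity checks (mean CRS equals the prevalence-weighted point sum) validate
the plumbing, not the epidemiology.

## Problem sizes

The shipped tests use 10,000 randomized input sets for the
verdict/expected-cost equivalence property, 10,000 Monte Carlo draws for
the probabilistic-sensitivity calibration checks and 100,000 replicates for
cohort parameter recovery — sizes at which the three-standard-error
acceptance bands are a few tenths of a percent wide while the whole suite
runs in well under a minute.

## Limitations

The framework is conceptual and literature-derived: the score weights are
not statistically derived, the parameter ranges are not a meta-analysis,
and no claims or registry data are ingested. The package consequently
validates internal consistency and published arithmetic, not predictive
performance. Costs are not inflation- or geography-adjusted; reimbursement
modeling is out of scope. The illustrative two-patient contrast sometimes
quoted with a ≈$560,000 differential does not follow from a single stated
arithmetic and is deliberately not used as a verification value.
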