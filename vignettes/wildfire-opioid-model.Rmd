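---
title: "A Monte Carlo model of wildfire-attributable opioid misuse via anxiety"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A Monte Carlo model of wildfire-attributable opioid misuse via anxiety}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fireopioid)
```

## The pathway being modeled

Exposure to a large wildfire raises the incidence and severity of anxiety in
the affected community, and anxiety is itself associated with substantially
higher odds of opioid misuse. `fireopioid` quantifies this mediation pathway
at the cohort level for U.S. young adults (ages 18–25): it asks how much the
past-year prevalence of opioid misuse would rise after a wildfire if the
only channel of effect were anxiety.

The model is deliberately simple. The population is partitioned into anxiety
strata, each stratum carries a misuse probability, and the population
prevalence is the stratum-weighted mixture. Nothing is longitudinal: both
anxiety and misuse are past-year prevalences, and a single wildfire event is
modeled. Counter-mechanisms (evacuation away from supply, shelter
environments, increased community support) are explicitly out of scope, as
are multi-event cumulative exposures.

## Parameters

| Parameter | Default | Units | Meaning |
|---|---|---|---|
| `a0` | 0.066 | probability | baseline past-year anxiety prevalence (ages 20–24) |
| `pi_target` | 0.053 | probability | baseline past-year opioid-misuse prevalence (ages 18–25); calibration target and fixed PR reference |
| `p0` | calibrated | probability | misuse probability absent anxiety — the one free parameter |
| `a1_spec` | Beta(10.5, 70) | probability | post-wildfire anxiety prevalence; mean 0.130, SD 0.037 |
| `or_spec` | lognormal, mean 3.04 / SD 1.07 | odds-ratio scale | misuse odds ratio given fire-related anxiety |
| `rr_s2`, `rr_s3` | 5 | risk-ratio scale | hypothetical risk ratios for wildfire-conditioned anxiety |
| `n_iter` | 50,000 | draws | Monte Carlo iterations |

The Beta and lognormal hyperparameters are taken as given; fitting them to
the underlying field studies is not a goal of this package. The risk ratio
of 5 is a hypothetical — the scenarios using it are sensitivity analyses,
and `sweep_risk_ratio()` exposes the full (affine) response.

## Scenario algebra

With `q(p, OR)` the probability obtained by scaling the odds of `p` by `OR`,
`a1` the (floored) post-wildfire anxiety prevalence and `a0` the baseline:

- baseline: `(1 - a0) p0 + a0 q(p0, OR)`
- S1 (anxiety incidence only): `(1 - a1) p0 + a1 q(p0, OR)`
- S2 (incident anxiety predisposed to misuse): `(1 - a1) p0 + a0 q(p0, OR)
  + (a1 - a0) min(1, RR p0)` — the pre-existing slice keeps the OR-implied
  probability; only the wildfire-incident slice receives the risk ratio.
- S3 (pre-existing anxiety worsens too): `(1 - a1) p0 + a1 min(1, RR p0)`.

Two consequences worth knowing. First, S2 and S3 are exactly affine in the
risk ratio below the saturation cap, with slopes `(E[a1] - a0) p0` and
`E[a1] p0`; their ratio at the default parameter point is about 2.02, so S3
rises roughly twice as fast. Second, the ordering S3 ≥ S2 ≥ S1 holds per
draw only when `RR p0` exceeds the OR-implied probability; at the default
parameters it holds in the mean.

## Calibration

`calibrate_p0()` solves `baseline_prevalence(p0, a0, OR) = pi_target` for
`p0`. The mixture is strictly increasing in `p0` and bounded above by the
value at `p0 = pi_target`, so bisection on `(0, pi_target]` converges
unconditionally; we use bisection rather than a derivative-based method
because the bracket is known and the function is cheap, and the default
tolerance is 1e-10 in prevalence units (far below the 2-significant-figure
reporting scale). Calibration uses the odds-ratio point estimate 3.04 — the
median of the source studies — rather than a Monte Carlo average. This
choice makes the calibrated `p0` (≈ 0.04745) reproduce the deterministic
worked values for S2 and S3 at the Beta-mean anxiety prevalence, and the
tests hold it to an independent `uniroot()` oracle.

## Distributional choices

The lognormal for the odds ratio is specified by its *natural-scale*
moments: mean 3.04 and SD 1.07 on the odds-ratio scale, converted by exact
moment matching (`lognormal_from_moments()`: μ = ln(m²/√(m²+s²)),
σ² = ln(1+s²/m²), giving μ ≈ 1.0535, σ ≈ 0.3418). A stated mean/SD pair is
ambiguous — it could also denote the log-scale location and scale — and the
two readings give very different spreads. We default to natural moments
because the implied central 95% odds-ratio range (≈ 1.5–5.6) is consistent
with the uncertainty-interval widths the model is meant to produce;
`lognormal_spec(..., parameterization = "log_location_scale")` selects the
other reading.

Sampled post-wildfire anxiety prevalences are floored at `a0` by default
(`floor_a1 = TRUE`): a wildfire is not allowed to lower anxiety prevalence.
The floor binds on about 2.4% of Beta(10.5, 70) draws. It also pins the
lower end of the S3 prevalence interval at `p0 (1 - a0 + RR a0)` (≈ 6.0% at
defaults), which is why that endpoint is essentially deterministic.

Prevalence ratios divide by the fixed calibration target `pi_target` by
default. The alternative, dividing by the same draw's baseline prevalence
(`pr_reference = "per-draw"`), shares the sampled odds ratio between
numerator and denominator; combined with flooring it guarantees PR ≥ 1 for
S1 on every draw with OR ≥ 1, and it pins the lower S1/S2 PR interval
endpoints at exactly 1. The fixed reference is kept as the default because
it is the convention the reported ratio summaries are defined under, but
users comparing against interval endpoints that hug 1.00 from above should
be aware the per-draw convention is likely what produced them.

## Monte Carlo mechanics

Each iteration draws one `(a1, OR)` pair; all four scenario prevalences and
their ratios are computed from the same pair, so scenario contrasts are
positively correlated within a draw. The anxiety and odds-ratio samples come
from separate substreams whose seeds are derived deterministically from the
run seed (a fixed Lehmer-style step), so adding a new output stream never
perturbs existing draws, and identical configurations reproduce draw tables
bit for bit. The two parameters are sampled independently; no correlation
structure between them is asserted.

Summaries report the mean and the 2.5th/97.5th percentiles using linear
interpolation between order statistics (`quantile()` type 7). The quantile
convention is a genuine degree of freedom, but at 50,000 draws the
alternatives move endpoints by well under 0.001, below every tolerance used
here. Machine output is kept at full precision; rounding to two significant
figures is left to the reader.

## The synthetic cohort as oracle

`simulate_cohort()` generates individuals with exactly the statistical
structure the cohort algebra assumes: one categorical draw assigns each
person to `none` / `pre_existing` / `incident` anxiety strata with masses
`1 - a1`, `a0`, `a1 - a0` (a single multinomial draw, not sequential
Bernoullis, so the stratum counts are exactly multinomial), then a Bernoulli
misuse indicator with the scenario's stratum probability. Its empirical
prevalence therefore converges to `scenario_prevalence()` at the same
parameter point — the tests require agreement within 3 binomial standard
errors at one million persons — and `recovery_experiment()` shows the
misuse odds ratio is re-estimated from the 2×2 table essentially without
bias (relative bias under 2% across 200 cohorts of 100,000) with
near-nominal Wald interval coverage.

This oracle validates the algebra, not the world: it inherits every
simplification of the cohort model (no covariates, no measurement error in
anxiety ascertainment, no time structure, exact Bernoulli outcomes). Passing
these tests says the formulas and the generator are mutually consistent; it
says nothing about how real post-disaster cohorts behave.

## Problem sizes and runtime

The default run is 50,000 iterations and completes in about a second; unit
tests use 2,000–5,000-draw runs and cohorts of 10⁵–4×10⁵, while the
acceptance-style checks use the full 50,000-draw run, million-person
cohorts, and 200 recovery replicates — the whole suite runs in well under a
minute. These sizes were chosen so Monte Carlo error is far below the
tolerances being asserted (the standard error of a scenario mean at 50,000
draws is about 3×10⁻⁵).

## Known limitations

- The two uncertain inputs are independent by assumption; any real
  correlation between post-fire anxiety prevalence and the misuse odds
  ratio is not represented.
- The risk ratios in S2/S3 are hypothetical constants, not estimates; the
  scenarios bound a mechanism, they do not measure one.
- The fixed-reference prevalence-ratio intervals for S1 extend below 1,
  which reads oddly for an exposure that cannot reduce anxiety here; see
  the per-draw reference discussion above.
- Results are conditional on the stated Beta/lognormal hyperparameters;
  re-deriving them from primary studies is out of scope.
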