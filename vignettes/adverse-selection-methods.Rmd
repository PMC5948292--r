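---
title: "Methods: simulating adverse selection in supplementary health insurance"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating adverse selection in supplementary health insurance}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the model implemented by `shisim`, the assumptions
behind it, the tunable parameters and their defaults, the numerical choices,
and what the synthetic-data generator does and does not emulate. It states
no empirical result beyond what the package's test suite and acceptance
script themselves compute.

## 1. The market model

A fixed population of `n` adults all hold one voluntary supplementary health
insurance (SHI) policy in the base year (uptake 100%). Enrolment then
evolves yearly through four flows:

* **opt out** — insured for whom holding the policy is *not* expected to be
  financially beneficial leave with probability `p` (independent Bernoulli
  draws each year);
* **keep** — all other insured stay;
* **opt in** — uninsured for whom the policy *is* expected to be beneficial
  return (deterministically by default);
* **stay out** — the remaining uninsured.

The four flows partition the population every year, and next year's insured
set is exactly `keep + opt in`; both identities are asserted in the tests.
If the insured pool ever empties, the trajectory terminates with a
market-collapse status instead of pricing on an empty pool.

**Profitability.** Holding the policy in year `t+1` is beneficial when

```
predicted claims(t+1) + RP >= premium(t+1),
```

with ties counting as beneficial, mirroring the risk-neutral purchase rule
("buy if predicted claims equal or exceed the premium"); a configuration
flag flips the tie rule. `RP` is the Pratt risk premium,
`RP = 0.5 * S² * r`, with `S²` the variance of expected SHI claims and `r`
the absolute risk-aversion coefficient. With the claims variances observed
over the study period (24,596–28,703 EUR²) and published `r` estimates
(0.00094–0.0067 per EUR), `risk_premium()` brackets RP between about EUR 12
and EUR 96; the simulation operates with a fixed `RP = 100` EUR rather than
recomputing the formula each year, which both keeps the decision rule stable
and acknowledges the substantial uncertainty in `r`. `risk_premium()`
remains available for sensitivity analyses. Classification always uses
unrounded values; euros are rounded only in reports.

**Premium.** The premium for year `t+1` is the mean realized year-`t` SHI
claims of the year-`t` insured pool, per risk group, times `1 + L` with a
constant loading `L = 0.23` across years and groups. Schemes:

| scheme | groups | fitted how |
|---|---|---|
| `community` | 1 | pool mean |
| `age_gender_28` | 14 age bands × 2 sexes | saturated OLS = cell means |
| `age_gender_quintile_140` | 28 × 5 prior-expense quintiles | saturated OLS = cell means |
| `individual` | one per person | own predicted claims |

A saturated dummy OLS is algebraically identical to per-cell means, so the
rates are computed as group-by means; the test suite verifies the
equivalence against `lm()` to 1e-9. The 140-class scheme is *fitted* on the
pool's year-`t-1` quintiles but *looked up* with a person's year-`t`
quintile, matching how an insurer estimates on last year's book and rates
next year's applicants. Cells emptied by a shrinking pool fall back to the
enclosing age–gender rate, then to the community rate, with a warning; this
chain is a package design choice for a situation the market description
leaves open. The 28 age–gender classes are not enumerated in the source
material either; the package uses the standard risk-equalization banding
18–24, 25–29, …, 80–84, 85+ crossed with sex, exposed in configuration.

Under individual rating the decision rule collapses to a closed form: the
policy is unprofitable exactly when `predicted > RP / L` (EUR 434.78 at the
defaults), independent of everyone else's decisions — which is why full
risk rating halts the spiral. The tests assert this set identity every year.

**Data looping.** Five cycle years of data cover a 25-year horizon by
repetition: simulation year `s` uses cycle year `s mod 5`. Individual
"health" therefore resets at each cycle boundary, which can kink the
trajectories there; the simulator is tested to cross boundaries without
crashing or leaking state. Opt-out draws are seeded per (replicate, year)
and consumed in fixed person order, so trajectories are reproducible and
independent of evaluation order; scenario grids share one seed, giving
paired draws across schemes and opt-out probabilities.

## 2. Claims prediction

Individual expectations come from a gamma GLM with log link of year-`t` SHI
claims on year-`t-1` information: age–gender class, PCG and DCG morbidity
flags, urbanization, ethnicity, the vigintile of prior basic-insurance
expenses and the decile of prior SHI claims. One model is fitted per cycle
year on the *full* baseline population and reused across loop cycles: a
person's expectation exists whether or not they currently hold the policy,
and refitting on the shrinking pool would make one person's risk signal
depend on others' enrolment. For the same reason the vigintile/decile/
quintile cutpoints are computed once on the full baseline population and
frozen inside the fitted predictor.

Numerical choices:

* **Zeros under a gamma likelihood.** The gamma support excludes zero, yet
  ~30% of person-years have no claims. Zeros enter the fit as EUR 0.01 —
  the simplest faithful reading of "gamma GLM on claims data with a point
  mass at zero". The substitution value is a documented argument
  (`zero_value`); a two-part estimator was considered and rejected as the
  default because the single GLM is the stated model.
* **Damped IRLS.** `stats::glm`'s IRLS only halves its step when the
  deviance becomes non-finite, and oscillates to failure on responses
  spanning EUR 0.01–35,000. The package fits by IRLS with step halving on
  *any* deviance increase (the same modification `glm2` makes), started
  from the Gaussian fit on log claims. On well-conditioned gamma data the
  fit agrees with `stats::glm` to 1e-6 (tested).
* **Quantile bins.** Cutpoints are inverse-ECDF quantiles (`type = 1`);
  ties go to the lower bin, so a zero point mass occupies the lowest bin
  and swallowed bins stay empty. Empty factor cells are dropped with a
  warning; prediction maps unseen levels to the reference level with a
  warning.

A gamma GLM with a correctly specified log-linear mean is consistent for
`E[y|x]` regardless of the true conditional shape, so the full-population
mean of predictions tracks the training-sample mean closely (tested at 5%),
and the predicted-claims decile table is strictly increasing with a wide
top-to-bottom spread on calibrated panels.

## 3. The synthetic population generator

No individual-level SHI claims data are publicly available, so the analysis
runs on seeded synthetic panels that emulate the statistical structure the
method needs:

```
spend_it ~ Bernoulli(plogis(a + u_i))            # any claims this year?
log y_it = c + m_i + u_i + e_it   (if spending)  # severity
m_i = covariate log-effects (age, sex, PCG, DCG, urbanization, ethnicity)
u_i ~ N(0, s_u²)   person frailty, constant over years
e_it ~ N(0, s_e²)  transitory noise
```

* The **frailty** `u_i` drives both the spend propensity and severity, so
  zero history, claim levels and year-to-year persistence are linked — the
  structure that makes prior-year claims predictive and adverse selection
  possible.
* The **variance split** targets an adjacent-year log-claims correlation of
  `persistence_rho` among two-year spenders: persistent variance
  (`var(m) + s_u²`) is set to `rho * sigma_log²` and transitory variance to
  the remainder.
* **Calibration by construction.** The spend intercept `a` and severity
  scale `c` are root-found on the realized draws so the empirical zero
  share and overall mean hit their targets (30%, EUR 221) almost exactly.
  `sigma_log = 0.95` was calibrated once so the claims decile profile
  matches the published actual-claims decile table (deciles 4–10 within
  15%); it is a generator constant, not a per-run fit.
* **Covariate effects are exactly multiplicative** on mean claims (spend is
  independent of observed covariates, and covariates are mutually
  independent), so each configured risk ratio — PCG × 2.0, DCG × 1.8,
  female × 1.25, e^0.022 per year of age — is the generator-true marginal
  effect. This makes parameter recovery well-defined: the GLM restricted to
  the covariate layout recovers `log 2` for PCG (tested at ±0.1 at
  n = 50,000). In the *full* layout the prior-claims bins absorb part of
  any time-constant effect (the prior year had the same PCG effect), so the
  conditional coefficient is attenuated by construction; recovery tests
  therefore use the covariate-only layout.
* **Tail cap.** Claims are capped at EUR 35,000, consistent with the
  largest observed claim in the study data (≈ EUR 33,250), so premium
  dynamics are not driven by synthetic outliers the data did not contain.
* Ages are fixed per person across the short panel; basic-insurance
  expenses share the frailty with their own scale and noise, since only
  their within-year rank (vigintile/quintile) is consumed downstream.
* One leading **prior-information-only year** (index 0) precedes the five
  cycle years, supplying prior-year covariates for the first cycle year —
  the role the year before the first simulated year plays in administrative
  data.

**What the generator does not emulate:** benefit-specific reimbursement
caps (the published decile table's tie groups arise from such limits; the
generator reproduces a zero point mass but not cap-induced ties at positive
values), demographic representativeness of any national population,
children (excluded by design), ageing or mortality over the horizon,
premium-dependent opt-out intensity, and coverage downgrading as an
alternative to exit. Passing tests therefore show that the *mechanism* —
selection on predictable claims under differential rating — behaves as
described on data with the published marginal structure, not that the
synthetic market reproduces any particular insurer's book.

## 4. Decile tables with ties

`decile_summary()` forms deciles on sorted claims without ever splitting a
tie group; each group belongs to the decile containing its lowest rank.
With ~30% zeros the zero group sits wholly in decile 1, neighbouring
deciles are empty, and a small partial group of near-zero positives lands
in decile 3 — the same qualitative shape as the published table, whose
exact tie-allocation rule is not recoverable from the printed shares.
Shares always sum to 100% and non-empty decile means are non-decreasing.

## 5. Parameters that matter

| parameter | default | units | why |
|---|---|---|---|
| `zero_claim_prob` | 0.30 | — | published share of person-years without SHI claims |
| `target_mean_claims` | 221 | EUR/yr | published overall mean |
| `sigma_log` | 0.95 | log-EUR | matches the published decile profile |
| `persistence_rho` | 0.65 | — | strong but imperfect year-to-year persistence; yields a Table-2-like predicted spread |
| `claims_cap` | 35,000 | EUR | just above the largest observed claim |
| `loading` | 0.23 | — | published market-average loading fee |
| `operating_risk_premium` | 100 | EUR | published operating value between the EUR 12–96 Pratt bounds |
| `opt_out_prob` | 0.05 / 0.10 | 1/yr | continuation of the observed ~1%/yr uptake decline; doubled for stronger selection |
| `horizon` | 25 | yr | published simulation horizon |

PCG prevalence defaults to 0.25 (the study sample over-represents PCG
membership relative to the general population), DCG to 0.08; urbanization
and ethnicity distributions are plausible for a western-European insured
portfolio and carry deliberately small effects.

## 6. Problem sizes and reproducibility

The acceptance-level checks run at the package's study scale — 50,000
insured, five cycle years, 20 Monte-Carlo replicates over 25 years — where
scheme orderings are stable under paired seeds; unit tests use 2,000–10,000
insured. All randomness flows from a single integer seed: the generator
restores the caller's RNG state, and simulation draws are derived per
(replicate, year). Identical spec and seed give byte-identical panels and
trajectories.

## 7. Known limitations

* The opt-out probability is exogenous: it does not grow with the
  premium–prediction gap, so simulated adverse selection is, if anything,
  an understatement; a gap-dependent rule is a natural extension.
* Opt-in is deterministic for everyone classified as beneficial; real
  re-entry is sluggish. A probabilistic opt-in switch exists
  (`opt_in_prob`).
* One insurer, one policy: no competition, switching, selective
  underwriting, or benefit redesign.
* The zero-substitution gamma fit is a pragmatic device; predicted *levels*
  below ~EUR 1 are artefacts of the device, though ranks — which drive the
  market dynamics — are unaffected.
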