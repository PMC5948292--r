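# shisim — adverse selection in voluntary supplementary health insurance

`shisim` is a microsimulation toolkit for studying the **adverse-selection
(death) spiral** in a voluntary supplementary health insurance (SHI) market,
and the capacity of **premium differentiation** to counteract it. It is aimed
at health economists and actuarial analysts who want a reproducible,
individual-level laboratory for enrolment dynamics: who keeps a voluntary
policy, who drops it, and what that does to the premium.

## The model

A population of adults holds an SHI policy at 100% uptake in a base year.
Each simulated year `t + 1`:

1. **Premium.** The insurer prices next year's policy from the current
   insured pool's realized claims: `premium(g) = (1 + L) * mean(claims in
   risk group g)`, with loading `L = 0.23`. Four rating schemes are
   supported: community rating (one group), 28 age–gender classes,
   140 age–gender × prior-expense-quintile classes (both as saturated OLS,
   i.e. cell means), and full individual risk rating.
2. **Expectation.** Each insured predicts next year's claims with a
   **gamma GLM (log link)** fitted on prior-year information: age–gender
   class, PCG/DCG morbidity flags, urbanization, ethnicity, the vigintile of
   prior basic-insurance expenses and the decile of prior SHI claims.
3. **Decision.** Holding the policy is *financially beneficial* when
   `predicted + RP >= premium`, where `RP` is the Pratt risk premium
   `RP = 0.5 * S^2 * r` (operating value EUR 100). Insured for whom the
   policy is *not* beneficial opt out with probability `p` (0.05 baseline,
   0.10 for stronger adverse selection); uninsured for whom it *is*
   beneficial opt back in.

Because low-risk exits raise the pool mean, community-rated premiums climb
and push out the next tier of low risks — the spiral. Refined rating prices
each group near its own expected claims, so few insured ever find the policy
unprofitable.

The study panel is synthetic: a seeded two-part claims generator (Bernoulli
spend indicator × lognormal severity with a persistent person-level frailty)
calibrated to a published claims profile — ~30% zero person-years, mean
EUR 221, heavy right tail capped at EUR 35,000, and strong year-to-year
persistence. Five cycle years are looped to cover a 25-year horizon.

## Worked example

```r
library(shisim)

round(risk_premium(24596, 0.00094))  # lower Pratt bound -> 12
round(risk_premium(28703, 0.0067))   # upper Pratt bound -> 96

panel <- generate_panel(population_spec(n_individuals = 20000, seed = 1))
scen <- run_scenarios(panel,
                      config = simulation_config(n_replicates = 5, seed = 7))
scen
```

```
<scenario_set>
  community                  p=0.05  final uptake  64.4%
  community                  p=0.10  final uptake  39.4%
  age_gender_28              p=0.05  final uptake  78.4%
  age_gender_28              p=0.10  final uptake  60.5%
  age_gender_quintile_140    p=0.05  final uptake  97.3%
  age_gender_quintile_140    p=0.10  final uptake  95.0%
  individual                 p=0.05  final uptake  97.7%
  individual                 p=0.10  final uptake  96.6%
```

Reading: under community rating the spiral erodes uptake to 64% after
25 years (39% with stronger adverse selection); 28 age–gender classes slow
it only moderately; 140-class rating stabilizes uptake above 95%, and full
individual risk rating behaves like the 140-class scheme. `uptake_plot(
scen$summary)` draws the trajectories with their 90% replicate bands.

An end-to-end run (panel CSV, per-year predictor JSONs, trajectory CSVs,
decile tables, uptake figure, digest manifest) is

```r
run_pipeline(system.file("extdata", "example-config.json",
                         package = "shisim"), "out/")
```

or, from a shell, the equivalent staged CLI:

```sh
Rscript "$(Rscript -e 'cat(system.file("scripts","shisim-cli.R",package="shisim"))')" \
  all --config config.json --out out/ --seed 1
```

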