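# plovermeta

Multistate mark–recapture estimation and stochastic metapopulation
viability analysis for a flow-disturbed shorebird system.

Piping plovers (*Charadrius melodus*) on the lower Platte and Missouri
rivers form a three-subpopulation metapopulation: human-created sand and
gravel mine habitat on the lower Platte (HC), the free-flowing Gavins Point
Reach of the Missouri (M1F), and the Lewis and Clark Lake reservoir (M2).
High-flow dam releases destroy M1F nesting habitat in the year they occur
and deposit fresh bare-sand habitat the year after, so that subpopulation's
demography, dispersal and carrying capacity all ride on the time since the
last high-flow event. This package provides, for ecologists working on
disturbance-driven metapopulations:

* an **Arnason–Schwarz multistate mark–recapture engine** — apparent
  survival φ, resight probability p and transition probability ψ estimated
  jointly from encounter histories by a hidden-state forward algorithm
  (logit links for φ and p, multinomial logit for ψ with "remain" as the
  reference), with design-matrix covariate models (age class,
  subpopulation, year, hatch date, banding age, reproductive success,
  pairwise distance, and high-flow indicator variables), fixed real
  parameters, QAICc ranking with Akaike weights, four-stage sequential
  model selection, model averaging, and Wald inference;
* an **individual-based viability simulator** with a high-flow disturbance
  state machine: floods at annual probability 0.05 at M1F only, zero
  reproduction in flood years, a post-flood carrying-capacity reset
  followed by 10–60 %/yr habitat decay, a 3-year window of low juvenile
  mortality after floods, environmental variation equal to 20 % of baseline
  mortality, and flow-state-dependent dispersal;
* a **synthetic-data generator** that reproduces the 2008–2013 study design
  (three strata at 182/241/30 km, the yearly chicks-fledged-per-pair table,
  the banding totals) so the full pipeline runs with no external data.

The growth-rate skeleton of the viability model is the two-stage female
projection λ = s_ad + s_juv · f/2, where f is chicks fledged per pair; the
simulator reduces exactly to this Leslie projection when stochasticity is
switched off (a tested invariant).

## Worked example

Simulate encounter histories under the canonical scenario, fit the
generating model, and inspect the dispersal coefficients:

```r
library(plovermeta)
sc  <- study_scenario()
dat <- simulate_histories(sc, cohort_sizes(total = 800, scenario = sc), seed = 1)
fit <- ms_fit(sc$generating_spec, dat$histories, dat$covariates, sc$distances)
wald(fit)
```

```
                   term estimate    se     z  lower  upper
        psi:(Intercept)   -1.676 0.249 6.724 -2.165 -1.188
        psi:agejuvenile    0.660 0.375 1.760 -0.075  1.395
           psi:distance   -0.010 0.002 5.231 -0.014 -0.006
      psi:hf_emigration    1.912 0.443 4.312  1.043  2.781
     psi:hf_immigration   -1.388 1.036 1.340 -3.419  0.642
 psi:posthf_immigration    0.918 0.365 2.513  0.202  1.634
```

Dispersal declines with distance (−0.010/km here; generating value
−0.011/km), emigration out of M1F jumps in the flood interval (logit effect
1.9 ≈ an odds ratio of 6.8), immigration into M1F is suppressed during the
flood and elevated the year after — each estimate within two standard
errors of the value used to generate the data.

Run the frozen viability scenario (1000 replicates × 100 years, ~half a
minute):

```r
pva <- run_pva(pva_fixture())
summary(pva)
```

```
         subpop extinction_probability extinction_se mean_years_to_extinction
 Metapopulation                  0.000         0.000                       NA
             HC                  0.000         0.000                       NA
            M1F                  0.446         0.016                   23.621
             M2                  0.000         0.000                       NA
     n20     n50    n100 lambda_deter lambda_stoch recolonizations
 205.345 199.988 200.216           NA        1.059              NA
 117.543 117.388 117.574        1.139        1.042               0
  26.809  24.972  24.435        0.949        1.274            2341
  60.993  57.628  58.207        1.046        1.037               0
```

The metapopulation as a whole is essentially extinction-proof over a
century (persistence rests on the stable human-created HC and M2 habitats),
but the naturally disturbed M1F subpopulation is extinct at year 100 in
~45 % of replicates, typically first winking out ~24 years in — when the
post-flood habitat has eroded away — and is repeatedly recolonized (2341
events across the 1000 replicates) by dispersers after the next flood
resets the habitat. Its deterministic growth rate is below one
(λ_deter ≈ 0.95), yet its realized stochastic growth exceeds one
(λ_stoch ≈ 1.27) because immigration rescues it: a disturbance-dependent
sink kept alive by connectivity.

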