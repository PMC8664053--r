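# hhsurvey

Design, simulation and evaluation of two-stage household health surveys.

Municipal health surveys commonly estimate the prevalence of health
determinants (self-rated health, use of primary-care services, blood-pressure
monitoring, ...) from a household sample drawn in two stages: primary sampling
units (PSUs) built from census tracts are selected systematically with
probability proportional to size (PPS), and households are then selected
systematically within each PSU at a fixed fraction, so that every household
shares the same overall inclusion probability (a *self-weighting* design).
`hhsurvey` implements the full methodology around such a design, for survey
statisticians planning a study and for methodologists evaluating one:

* **Planning.** For a population stratified by sex and seven age groups, the
  per-stratum person/household ratio `r = N/D` determines the households
  needed to expect at least `m` individuals per stratum,
  `round(m·D/N)`; the base sample `n₀` is the maximum over strata, and the
  field sample is inflated for an anticipated response rate,
  `n = ⌊n₀/0.90⌋`.  Expected precision is profiled through
  `se = √(p(1−p)/n)`, the 95% CI `p ± 1.96·se` and the coefficient of
  variation `Cv-p̂ = 100·se/p̂` (the usual adequacy rule is `Cv < 20%`).
* **Frame construction.** Census tracts (~300 households each) are split
  and/or grouped in code order until the CV of PSU sizes is ≤ 10%.
* **Sampling.** Systematic PPS selection of `a` PSUs over the cumulated
  household counts, then systematic household selection with the fixed
  second-stage fraction `b/Mᵢ` applied to the updated field listing `Mᵢ′`
  (takes grow with the sector), giving the global fraction
  `f = (a·Mᵢ/ΣMᵢ)·(b/Mᵢ) = a·b/ΣMᵢ` and design weight `1/f`.
* **Fieldwork.** Household contact outcomes under a three-visit protocol
  (refusal at first contact, absence after all visits fail) and the
  non-response rates NRR-Total = x/X, NRR-Refusal = xᵢ/X, NRR-Absence = x_z/X.
* **Estimation.** Design-based proportions with Taylor-linearized
  (ultimate-cluster) variances, `Cv-p̂`, the design effect
  `deff = V_design/(p̂(1−p̂)/n)` (Kish planning approximation
  `1+(b̄−1)ρ`), and predictive-mean-matching imputation for indicators with
  up to 20% missing values.
* **Synthetic frames and experiments.** A census-frame generator with
  controllable prevalence, intra-cluster correlation ρ and missingness, and
  a replication harness measuring CI coverage, deff distributions and
  non-response, end to end.

The packaged reference inputs are the 2010 IBGE census counts for the
municipalities of Teresina (210,093 households) and Picos (16,944
households) in Piauí, Brazil, stratified by sex and age group.

## Worked example

```r
library(hhsurvey)

cen  <- reference_census()
plan <- sample_plan(subset(cen$population, municipality == "Teresina"),
                    cen$households["Teresina"])
plan
#> Household sample-size plan
#>   municipal households (D): 210,093
#>   minimum individuals per stratum: 30
#>   base sample n0: 578 households (limiting stratum: F 3-4)
#>   inflated for 90% response: n = 642 households
#>   expected individuals: 2,111 (M 981, F 1,130)
```

The scarcest stratum (girls aged 3–4, about 0.052 per household) drives the
whole plan: 578 households are needed to expect 30 of them, 642 after
allowing for 10% non-response, and those households are expected to yield
2,111 individuals across all strata.

A full synthetic run — generate a municipality, build PSUs, draw, field,
estimate:

```r
cfg <- frame_config(n_tracts = 40,
                    indicator_specs = list(
                      indicator_spec("chronic", 0.3, icc = 0.03)),
                    seed = 11)
fr <- generate_frame(cfg)
pf <- build_psus(fr)                    # size CV 0.052
hh <- assign_households(pf, fr$households)
dr <- two_stage_draw(pf, hh, a = 12, b = 20, seed = 3)
dr
#> Two-stage draw: a = 12 PSUs, b = 20 planned households/PSU
#>   global fraction f = 12*20/11,763 = 0.020403 (weight 49.0)
#>   households drawn: 240

fw <- simulate_fieldwork(dr$households$household_id,
                         field_params(p_refusal = 0.2, p_absent_visit = 0.25,
                                      seed = 5))
nrr_report(fw)
#> Household non-response: 47 of 240 (NRR-Total 19.6%)
#>   refusal: 43 (17.9%), absence: 4 (1.7%)

ds <- survey_dataset(dr, fr$persons,
                     fw$household_id[fw$outcome == "interviewed"])
estimate_proportion(ds, "chronic")
#> chronic: p = 27.6% (95%CI 22.0-33.1), Cv 9.2%, deff 2.15, n = 671 (12 PSUs)
```

The estimate is read as: prevalence 27.6% with a design-based 95% CI of
22.0–33.1%; `Cv` 9.2% is comfortably below the 20% precision rule; the
design effect 2.15 says the clustered sample is equivalent to a simple
random sample about half its size for this indicator (the frame was
generated with within-tract correlation, so a deff above 1 is expected).

`run_survey_experiment()` wraps this whole chain over many replicates, and
`planning_table()` lays out the planning arithmetic for any
stratum-population table in the familiar five-block form.

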