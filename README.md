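# dtmdd

Population pharmacokinetics of the anti-TNF-alpha antibody infliximab with
**target-mediated drug disposition (TMDD) in both the central and the
peripheral compartment**, under the quasi-steady-state (QSS) approximation.

Infliximab binds TNF-alpha with high affinity; the drug-target complex is
cleared by the immune system, so the target pool ("antigen mass", circulating
plus tissue-expressed) contributes a saturable elimination pathway. In
inflammatory bowel disease (IBD) the clinically interesting question is
whether the target is durably blocked not in blood but in a deep (peripheral)
compartment. This package implements, as a tested and reusable pipeline, the
double central-peripheral TMDD model that addresses this question: the
structural ODE model, the nonlinear mixed-effects population layer, a
synthetic-trial generator for the two study designs (a rich ankylosing
spondylitis cohort used as linear reference and a sparse trough/peak IBD
cohort), maximum-likelihood estimation with the model-building and
covariate-selection procedures, VPC/NPDE diagnostics, and the target-occupancy
simulation study. It is aimed at pharmacometricians who want to re-estimate,
extend or simulate from this model class without NONMEM/Monolix.

## Model

States are total drug and total target in each compartment (nM). With
unbound drug `C` the positive QSS root of
`C^2 + (RT + KSS - CT) C - KSS CT = 0`,

    dCT/dt  = In(t) - (CL/V1) C - (Q/V1) C + (Q/V2) CP - kintC (CT - C)
    dRTC/dt = kinC - kout (RTC - (CT - C)) - kintC (CT - C)
    dCPT/dt = (Q/V1) C - (Q/V2) CP - kintP (CPT - CP)
    dRTP/dt = kinP - kout (RTP - (CPT - CP)) - kintP (CPT - CP)

with `kin = R0 kout`, infusions as zero-order input `In(t)`, exponential
interindividual variability on `V1, CL, V2, R0C, R0P`, covariates (body
weight, sex, ulcerative colitis) on the log scale, and combined
additive-proportional residual error. Target occupancy is summarised by the
unbound/total target ratio, `R/RT = KSS/(KSS + C)` under QSS. The reference
parameter estimates (central: `R0C` 3.3 nM, `KSSC` 15.4 nM, `kintC`
0.17/day; peripheral: `R0P` 0.46 nM, `KSSP` 0.49 nM, `kintP` 0.0079/day;
`kout` fixed at 20/day) ship as `infliximab_population()`.

## Worked example

Simulate the typical IBD subject (female, Crohn's disease, 66 kg) under
5 mg/kg infusions at weeks 0, 2, 6, 14, 22 and look at drug and target:

```r
library(dtmdd)
pop <- infliximab_population("final")
typ <- typical_params(pop, subject_covariates(66, "F", "CD"))
reg <- dose_events(7 * c(0, 2, 6, 14, 22), dose_from_weight(66, 5))
prof <- simulate_profile(typ, reg, times = seq(0, 210, by = 0.1))
round(subset(prof, time_day %in% c(14, 42, 98, 154, 210),
             c(time_day, conc_mgL, RTC_nM, RTP_nM, ratio_C, ratio_P)), 3)
#>       time_day conc_mgL  RTC_nM  RTP_nM ratio_C ratio_P
#> 141         14   25.186  37.177  83.170   0.083   0.004
#> 421         42   20.120  30.487 122.526   0.102   0.005
#> 981         98    7.585  13.895  44.100   0.232   0.012
#> 1541       154    5.717  11.331  32.017   0.286   0.016
#> 2101       210    5.440  10.948  30.313   0.297   0.017
```

Troughs (`conc_mgL`) fall from 25 to ~5.4 mg/L across the maintenance
cycles; total target (`RTC_nM`) accumulates far above its 3.3 nM baseline
(maximum ~85 nM, a 26-fold rise) because the drug-target complex is cleared
much more slowly than free target; and the central occupancy ratio
(`ratio_C`, unbound/total target) re-escapes toward 30% at the late troughs
while the peripheral ratio (`ratio_P`) stays below 2% - the peripheral
compartment remains essentially fully blocked.

A population view of the same scenario (1000 virtual subjects, covariate
distributions of the simulation protocol):

```r
ens <- run_scenario(scenario_spec(n = 1000), pop, seed = 1)
r <- ratio_at_reference_conc(ens, ref_conc = 5)   # pooled at C = 5 mg/L
round(100 * c(central = r$central, peripheral = r$peripheral), 1)
#>    central peripheral
#>       31.5        1.7
trough_ratio_metrics(ens)[3:4, c("time_day", "central_median",
                                 "peripheral_median")]
#>   time_day central_median peripheral_median
#> 3     97.9          0.317            0.0190
#> 4    153.9          0.375            0.0250
```

Generate a synthetic joint study and fit the double-TMDD model:

```r
ds <- bind_datasets(
  generate_dataset(study_design("as_rich"),  pop,  25, seed = 1),
  generate_dataset(study_design("ibd_rich"), pop, 125, seed = 2,
                   id_offset = 1000))
fit <- fit_tmdd(ds, "double_tmdd", kout = 20, init = pop,
                control = fit_control(maxit = 100, polish = 2))
fit
```

`structural_ladder()`, `kout_grid_select()` and `covariate_stepwise()`
reproduce the model-building procedure; `gof_table()`, `vpc()` and `npde()`
the diagnostics.

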