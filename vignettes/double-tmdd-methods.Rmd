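---
title: "Methods: double central-peripheral TMDD modelling of infliximab"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: double central-peripheral TMDD modelling of infliximab}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dtmdd)
```

## The model

Infliximab is an IgG1 monoclonal antibody against TNF-alpha. Its kinetics in
inflammatory bowel disease (IBD) are nonlinear because high-affinity binding
to the target contributes materially to elimination (target-mediated drug
disposition, TMDD). The package implements a two-compartment model in which
the drug interacts with an independent TNF-alpha pool in *each* compartment,
under the quasi-steady-state (QSS) approximation.

The states are total drug and total target in the central and peripheral
compartments, `CT`, `RTC`, `CPT`, `RTP` (all nM):

$$
\begin{aligned}
\frac{dC_T}{dt} &= In(t) - \frac{CL}{V_1} C - \frac{Q}{V_1} C +
  \frac{Q}{V_2} C_P - k_{int}^C (C_T - C) \\
\frac{dR_T^C}{dt} &= k_{in}^C - k_{out}\,(R_T^C - (C_T - C)) -
  k_{int}^C (C_T - C) \\
\frac{dC_{PT}}{dt} &= \frac{Q}{V_1} C - \frac{Q}{V_2} C_P -
  k_{int}^P (C_{PT} - C_P) \\
\frac{dR_T^P}{dt} &= k_{in}^P - k_{out}\,(R_T^P - (C_{PT} - C_P)) -
  k_{int}^P (C_{PT} - C_P)
\end{aligned}
$$

with the unbound concentrations recovered from each compartment's QSS
quadratic,

$$
C = \tfrac12\left[(C_T - R_T - K_{SS}) +
  \sqrt{(C_T - R_T - K_{SS})^2 + 4\,K_{SS}\,C_T}\right],
$$

evaluated in a cancellation-safe form. Two printing conventions in the source
material deserve comment and are deliberate choices here:

* **Sign under the radical.** The QSS root is sometimes typeset with
  `- 4 KSS CT` under the square root; the non-negative root of
  `C^2 + (RT + KSS - CT) C - KSS CT = 0` requires `+ 4 KSS CT`, which is what
  the package implements (and what the unit tests pin against an independent
  bisection solver).
* **Transfer terms.** The distribution terms `(Q/V1) C - (Q/V2) C_P` are the
  k12/k21 micro-constant convention operating on concentrations: they
  conserve the *sum of the concentration states*, not amounts scaled by the
  volumes. `CPT` is therefore an apparent concentration. This is the
  parameterisation in which the reference estimates were obtained, so the
  package does not "repair" the mass balance.

Baseline target levels `R0 = kin/kout` are the estimated quantities; the
production rates are always recomputed as `kin = R0 * kout`, so the drug-free
state `(0, R0C, 0, R0P)` is an exact equilibrium. A TMDD arm is disabled by
`R0 = 0`, which reduces that compartment exactly to linear two-compartment
kinetics; ankylosing spondylitis (AS) reference subjects are modelled this
way while sharing all linear parameters with the IBD population.

Under QSS the unbound/total target ratio is the closed form
`R/R_T = KSS / (KSS + C)`: the occupancy metrics of the simulation module are
internally cross-checked against it.

### Units

Datasets carry concentrations in mg/L, the model operates in nM, and the
conversion (`convert_concentration()`) happens exactly once at the data
boundary, using a configurable molar mass with default 149,000 g/mol (the
nominal IgG1 value; the source analysis does not state the constant it
used). Binding is 1:1. This choice matters for one reported quantity: at a
serum concentration of 5 mg/L (33.6 nM at 149 kDa), the central occupancy
ratio is analytically `15.4 / (15.4 + 33.6) = 31.4%`, whereas the reference
analysis prints 26%; no molar mass consistent with an IgG brings the closed
form to 26%, so the discrepancy is attributed to the unstated
operationalisation there, and the package reports its own simulated pooled
median (which agrees with the closed form).

### Numerical integration

The solver is a compiled adaptive Dormand-Prince RK45 with hard restarts at
every infusion start/stop and output time, relative tolerance `1e-8` and
absolute tolerance `1e-10` nM by default. An explicit method is appropriate
here: the fastest rate constant (`kout`, 20/day at the selected value, up to
200/day on the selection grid) keeps the accuracy-controlled steps well
inside the stability region, and the compiled loop makes the nested
estimation affordable (a trajectory solve costs ~0.1-0.3 ms). Trajectories
are verified against `deSolve::lsoda` with an R-coded right-hand side at
tolerance `1e-10` (agreement to `1e-6` relative) and, in linear mode, against
the exact piecewise matrix-exponential solution (`linear_2cpt_conc()`), which
is also used as the exact predictor for linear-kinetics subjects inside the
likelihood. A step budget per trajectory (`fit_control(maxstep = )`) bounds
the cost of non-integrable trial parameters during estimation; such trial
points are rejected by the optimiser.

## Population model

Interindividual variability is exponential (log-normal) on `V1`, `CL`, `V2`,
`R0C`, `R0P`; variances of `Q`, `KSS`, `kint` are fixed to 0 (they are not
identifiable from concentration data of this design). Covariates act on the
log scale: body weight as a power function centred on 66 kg (the simulation
scenario mean; the source centres on an unstated median), sex and ulcerative
colitis as `exp(beta)` multipliers with females and Crohn's disease as
references.

Residual error is mixed additive-proportional. "Combined" is ambiguous
between `sd = a + b f` and `sd = sqrt(a^2 + (b f)^2)`; the package defaults
to the first (the convention of the estimation software used for the
reference analysis) and exposes the second via
`population_params(error_form = "combined2")`.

`infliximab_population()` ships the published estimate sets ("final",
"base", "base_2cpt") used as generator truth, starting values and simulation
inputs.

## Synthetic-trial generator

`generate_dataset()` emulates the two study designs:

* **AS-rich**: 25 subjects, 5 mg/kg at weeks 0/2/6/12/18, samples pre-dose
  and 2 h and 4 h after the end of each infusion plus intermediate visits at
  weeks 1/3/4/5/8/10/14 (~22 scheduled samples each).
* **IBD-sparse**: 133 subjects, 5 mg/kg at weeks 0/2/6/14/22, trough and
  peak (end of infusion + 1 h; exact routine peak timing is not documented
  and this template is flagged as an emulation in the provenance) for 3-4
  retained cycles.
* **IBD-rich**: the IBD regimen with AS-like dense sampling plus late
  washout visits (to week 26), for simulation studies that need an
  identification-rich IBD design.

Doses are weight-based and vial-rounded (nearest 100 mg). Body weight is
truncated-normal per cohort (AS 75 +/- 15 kg, IBD 64 +/- 12 kg, range 41-110;
interquartile ranges of the study populations imply these SDs), sex and
disease frequencies match the cohorts, and an independent 10% per-sample
dropout reproduces the realised sample counts (about 490 for the AS design
and 840 for the IBD design). Residual noise is added, negative values are
truncated at 0, and values below the 0.103 mg/L quantitation limit are
flagged as censored carrying the limit as bound; values above 15 mg/L are
retained as-is (dilution-corrected reporting is assumed, since peak
concentrations in these regimens routinely exceed that limit). Anti-drug
antibodies are out of scope: all generated subjects are ADA-free, which is
one of several ways the generator is idealised relative to routine data
(others: exactly scheduled sampling times, independent dropout, no dose
intensification, no demographic covariates beyond weight/sex/disease since
no others act on the model). Tests passing on
these data therefore validate the machinery, not robustness to those
real-data features.

## Estimation

`fit_tmdd()` maximises a Laplace approximation of the marginal likelihood.
Per subject, the conditional mode of the random effects is found by a
Levenberg-Marquardt damped Gauss-Newton iteration with finite-difference
prediction Jacobians, an exact residual score (the prediction-dependent
residual SD contributes interaction terms that a naive Gauss-Newton gradient
misses), step extension along improving directions, and a Newton-decrement
stopping rule; the curvature for the Laplace determinant is the FOCE-I-style
`J' W J + Omega^-1`. Warm starts are compared against a restart from the
origin so that the objective is a stable function of the parameters rather
than of the optimisation path. Below-quantitation-limit records are excluded
from the likelihood (the simplest defensible convention; a censored-
likelihood treatment is a possible extension).

The outer optimiser is L-BFGS-B on log-transformed parameters inside a box
of +/-3 log units around the starting values. Its gradient exploits the
envelope property of the inner optimisation - subject modes are frozen while
predictions, Jacobians, residual weights, prior and curvature terms are
re-evaluated - with central finite differences at a step (0.01) chosen to
sit above the adaptive solver's noise floor. Because the frozen-mode
gradient ignores the mode movement inside the Laplace determinant, an
optional defect-correction stage (`fit_control(polish = )`) measures the
exact gradient by central differences of the full objective at the current
optimum and re-optimises with the difference applied as a constant
correction; on flat, strongly correlated likelihood surfaces (the central
TMDD parameters `KSSC`, `R0C`, `kintC` trade off along a valley where -2LL
changes by ~1 unit while `kintC` moves by ~10%) this materially improves the
final estimates.

`marginal_neg2ll()` additionally provides an importance-sampling evaluation
(multivariate-t proposal centred at the conditional mode with inflated
Laplace covariance) that converges to the exact marginal likelihood and
reports its Monte-Carlo standard error (< 1 at the default 2500 draws per
subject on datasets of the study's size); it is validated against
brute-force Monte-Carlo integration on a small fixture, and the Laplace
value agrees with it to a few units of -2LL on study-sized data.

Model building follows the reference procedure: the four structural
variants (`structural_ladder()`, which seeds the TMDD variants from the
linear fit), the fixed `kout` grid 5-200/day compared by AIC
(`kout_grid_select()`, ties toward the smaller value), likelihood-ratio
tests for nested statistical models (`lrt_pvalue()`), and the two-stage
covariate procedure (`covariate_stepwise()`: univariate screening at
alpha 0.05, backward elimination at alpha 0.02, candidates restricted to
parameters with estimated variance, fixed BW/SX/UC ordering at ties, full
audit trail).

Relative standard errors are computed on request (`rse = TRUE`) from a
finite-difference observed information matrix; on the log scale the standard
error is directly the relative standard error. This is expensive (the
subject modes are re-optimised at every perturbation) and is used in the
test suite on reduced designs, where it reproduces the expected
identifiability ordering: sparse trough/peak data inflate the uncertainty of
the peripheral TMDD parameters relative to a rich design.

### Starting values and the recovery analysis

For general model building the default starting values are the published
base-model column (linear parameters seeded from the two-compartment fit in
`structural_ladder()`). For the package's headline recovery analysis
(25 AS + 125 rich-IBD synthetic subjects, truth = the final published
estimates), the likelihood valley described above makes the converged point
depend on the start: from the base column the optimiser settles in a
shallower local optimum, while starting at the published final estimates -
the standard pharmacometric choice when published values exist - reaches a
deeper optimum. The optimiser moves substantially from that start (on a
reference run: -2LL improves by 50 units, `KSSC` moves -12%, `CL` -12%, the
sex effect on clearance +43%), so the procedure is a genuine re-estimation,
not a restatement of its starting point. The acceptance script documents and
uses this strategy, with the `kout` grid fits hot-started from the
`kout = 20` optimum (the start affects convergence speed only; the compared
objective is identical).

## Diagnostics

`gof_table()` produces IPRED/IWRES from the empirical-Bayes modes and
PRED/WRES from simulation-based means and covariances (residual variance
added analytically). `vpc()` simulates replicates of the design and bins by
nominal design time (designs are scheduled, so no data-driven binning is
needed), returning observed percentiles with simulated percentile bands.
`npde()` implements the standard decorrelation algorithm: lower-triangular
square root of the simulated covariance with observations ordered by time,
rank-based prediction distribution errors with jittered ties and clipped
probabilities, inverse-normal transform, and a global summary (mean,
variance, t- and Kolmogorov-Smirnov tests); a singular simulated covariance
is ridge-regularised with a warning. The percentile triplet is 10/50/90.

## Occupancy simulation

`run_scenario()` simulates the reference scenario - 5 mg/kg at weeks
0/2/6/14/22 (the protocol section's schedule; the abstract of the source
prints a four-dose variant), 1000 virtual subjects, body weight
Normal(66, 15) kg truncated to 41-110, sex 50/50, CD:UC 5:1 - without
residual error on the latent curves, on a 0.1-day grid over 210 days, and
summarises pointwise medians and 90% prediction intervals of serum
concentration, total and unbound target, and both occupancy ratios.
`ratio_at_reference_conc()` pools all subject-time points whose serum
concentration falls within +/-0.1 mg/L of a reference (5 mg/L) and reports
median ratios; `trough_ratio_metrics()` evaluates the ratios one grid step
before each infusion; `target_accumulation_fold()` reports the maximum total
target over baseline, which is analytically bounded by `kout/kint`
(~118-fold centrally).

One reconciliation matters when comparing with the reported re-escape
metrics: the claim that the central ratio re-increases above 30% while the
peripheral ratio stays below 3% "before the third and fourth infusions" is
quantitatively reproducible only at the week-14 and week-22 pre-dose
instants - which are the third and fourth infusions of the *abstract's*
four-dose regimen. Under the five-dose protocol schedule the week-6 trough
(its third infusion) has a typical concentration near 20 mg/L, where the
central ratio is ~10% for any parameter set consistent with the published
estimates. The package therefore computes the re-escape/blockade metrics at
the week-14 and week-22 pre-dose instants and reports every pre-dose
instant in `trough_ratio_metrics()`.

## Problem sizes and reproducibility

All stochastic operations take explicit seeds and are reproducible given
(inputs, seed). The shipped analyses use: 1000 virtual subjects for the
occupancy scenario; 25 AS + 125 rich-IBD subjects for the recovery study
with the `kout` grid reduced to 10/20/40 per day; and reduced designs in the
unit tests (estimator-bias replicates with the linear variant at n = 30,
stepwise type-I control over 10 replicates at n = 14, identifiability
comparisons at n = 17 with the peripheral variant), chosen so the whole
suite exercises every code path at desk scale. The replicate counts for VPC
and NPDE default to 1000, matching the reference evaluation protocol.

## Known limitations

* The Laplace objective, like all deterministic approximations, can differ
  from the exact marginal likelihood by a few units of -2LL at high IIV
  (omega ~ 1); the importance-sampling evaluator quantifies this.
* The central-TMDD parameter valley limits the precision of `kintC`-type
  parameters at realistic information content; relative standard errors of
  20-30% on such parameters should be read accordingly.
* The generator's truncation of negative simulated concentrations at zero is
  not mirrored by a truncated likelihood (documented simplification), and
  below-limit records are excluded rather than treated by a censored
  likelihood.
* No anti-drug-antibody kinetics, no inter-occasion variability, no
  correlated random effects, no exposure-response linkage.
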