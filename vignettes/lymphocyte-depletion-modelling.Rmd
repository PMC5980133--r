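---
title: "Modelling antibody-induced lymphocyte depletion in cynomolgus monkeys"
author: "lymphodep authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling antibody-induced lymphocyte depletion in cynomolgus monkeys}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lymphodep)
```

## The problem

Cytolytic anti-CD38 monoclonal antibodies deplete CD38-expressing blood
cells — most strongly natural killer (NK) cells, less so B and T
lymphocytes. Before a first-in-human (FIH) trial, the exposure–effect
relationship has to be quantified in a cross-reactive species; the
cynomolgus monkey is the usual choice. `lymphodep` implements the
population PK-PD machinery for this setting: a nonlinear-elimination PK
model, three cell-type-specific depletion models, a trial simulator, a
synthetic-data generator, likelihood-based estimation,
noncompartmental analysis (NCA), and allometric monkey-to-human
scaling. Everything a user needs is exposed as R functions; the package
is a modelling library, not a shell tool, so the functions, this
vignette and `scripts/acceptance.R` are the interface.

## The PK model

Drug disposition follows a two-compartment model with first-order
absorption from a subcutaneous (SC) depot and, crucially, target-mediated
drug disposition (TMDD): the antibody binds a turning-over target pool in
the central compartment and the complex is internalised. Binding is
reduced with the quasi-steady-state (QSS) approximation, under which the
free concentration $C$ solves

$$C + \frac{R_{tot}\,C}{K_{SS} + C} = C_{tot},$$

a quadratic with the closed-form root implemented in
`qss_free_concentration()`. The states are drug amounts in depot,
central and peripheral compartments plus the total target concentration
$R_{tot}$, with balance equations in `pk_rhs()` (and compiled in C for
the integrator). Target synthesis ($K_{SYN}$), degradation ($K_{DEG}$)
and complex internalisation ($K_{INT}$) give the drug-free equilibrium
$R_{tot}(0) = K_{SYN}/K_{DEG} \approx 8.85$ u/L.

Parameter notes:

* `F_logit` — bioavailability on the logit scale so estimates stay in
  (0, 1); the typical value corresponds to $F = 0.227$.
* `KSS` — although the source table prints its unit as 1/day, the QSS
  algebra requires a concentration; it is treated as µg/mL (as the
  composite $(K_{OFF}+K_{INT})/K_{ON}$ must be). This is deliberate and
  assumed to be a table typo.
* Receptor units — "u/L" is coupled 1:1 to µg/mL: one unit binds one
  µg/mL-equivalent of drug. No molar conversion is published.
* `THETA_ROUT` — the SC route shrinks the apparent central volume
  proportionally: $V_C^{SC} = V_C (1 + \theta_{ROUT})$, 0.141 L → 0.043 L.
* The reported concentration for fitting and NCA is the *free*
  concentration (what an anti-idiotypic capture ELISA sees); the PD
  models are driven by the same free concentration. This matters only
  below a few µg/mL, where an appreciable fraction of drug is
  target-bound. The convention is a modelling choice: the source
  publication does not state whether its assay or PD driver is free or
  total drug.

Doses are events: IV boluses increment the central amount, SC doses
add $F \times$ amount to the depot at dose time (equivalent to
fractional absorption for a first-order depot, and simpler to handle),
and infusions are zero-order inputs. The integrator (`lsoda`,
relative tolerance $10^{-8}$, absolute $10^{-10}$ by default) restarts
at every dose time and infusion end; an observation scheduled exactly at
a dose time is reported predose.

```{r pk-example}
p <- monkey_pk_typical()
simulate_pk(p, dose_events(0, 9), times = c(0.01, 1, 7, 28, 42))
terminal_halflife(p$CL, p$VC, p$Q, p$VP)
```

The implied terminal half-life, 10.3 days, sits inside the 4.75–11.2 day
range obtained noncompartmentally from the single-dose monkey studies.

## The PD models

All three models share an $E_{max}$ effect
$E(c) = E_{MAX}\, c / (C_{50} + c)$. Hill exponents were tested and
rejected during the original model development, so they default to 1
here; `pd_params(..., hill =)` exposes the variant but nothing in the
package turns it on.

* **NK cells** (`nk_simulate()`): turnover (indirect-response) model,
  $dNK/dt = K_{IN} - K_{OUT}\,NK - NK \cdot E(c)$, with the structural
  tie $K_{OUT} = K_{IN}/BL$ to the individual baseline. $E_{MAX}$
  (414.6/day) dwarfs $K_{OUT}$ (20.4/day at the median baseline), which
  is why NK depletion is nearly complete at modest exposure.
* **B cells** (`bcell_simulate()`): four transit compartments with
  common rate $4/MTT$ feeding the circulating pool; the drug stimulates
  elimination of circulating cells only. Because the published
  equations set the proliferation rate equal to the transit rate, the
  upstream chain is constant in time; the chain is nonetheless carried
  in full as a documented structural quirk. The transit delay puts the
  B-cell nadir days after the concentration peak.
* **T cells** (`tcell_response()`): memoryless direct response
  $T(c) = BL\,(1 - E_{MAX}\, c/(c + C_{50}))$ with $E_{MAX} = 0.4656$:
  only about half the T-cell pool is depletable. The known misfit of
  this model immediately after a first high dose is *not* corrected —
  fidelity to the published model is preferred over ad-hoc patches.

Model-implied orderings that the tests assert: time-to-nadir
T ≤ NK < B after a single dose; closed-form steady states under
constant exposure (NK $8.95\%$ of baseline at $c = C_{50}$, B
$28.7\%$); exact homeostasis at zero exposure.

```{r pd-example}
prof <- simulate_pk(p, dose_events(0, 9), seq(0, 42, by = 0.1))
nk_simulate(pd_typical("NK"), prof, c(1, 7, 14, 28))
```

## Population simulation and the synthetic-data generator

`simulate_trial()` layers lognormal between-subject variability
(`PAR_i = TVPAR e^{\eta_i}`, diagonal $\omega$) and residual error
(combined additive+proportional for PK, proportional-only for cell
counts) onto the structural models, for any `study_design()`. The
printed "%CV" magnitudes are taken as $\omega$ directly; the
alternative $\omega = \sqrt{\log(1+CV^2)}$ differs by under 9% at these
magnitudes and is available via `convention = "log_sd"`. Whether the
published PD residual magnitudes (0.2905, 0.136, 0.1343) are variances
or SDs is not stated; the package defaults to the NONMEM SIGMA
convention (variances), switchable with `residual_spec(pd_as_sd =)`.
Under the variance reading the implied within-animal placebo CV for B
cells is ~37%, under the SD reading ~14%; the published placebo
observation (27%) lies between the two, which is why the toggle exists.

The generator (`generate_study_dataset()`) ships templates for the
eight monkey studies — animal numbers, dose levels, routes, dosing
frequency and per-animal sample counts are as published; the clock
times of the samples are invented to match the published counts, since
they are not printed. Baselines are sampled lognormally, calibrated by
`lognormal_from_median_iqr()` to the printed medians and IQRs (counts
are positive and right-skewed; the lognormal is a choice, not a
published fact). CD38-positive fractions are truncated-normal on [0, 1]
with the latent mean calibrated so the truncated mean matches the
printed mean (naive truncation would shift the NK mean by 0.026).
Body weights are uniform on 2.1–4.7 kg — only the range is published.

Anti-drug antibodies (ADA) emerged over time in the repeated-dose
studies; only per-sample flags and a qualitative description exist.
The onset model here is therefore an explicit fabrication, fully
config-exposed (`ada_config()`: seroconversion probability 0.3,
earliest onset day 28, exponential delay with mean 14 days), producing
within-animal monotone flags. Flags exist to exercise the
flag-and-exclude workflow (`exclude_flagged()`), which also drops
below-quantification PK samples (retained in files, excluded from
fitting; limit 0.05 µg/mL, 0.061 in study 1) and PD samples within 8 h
of a dose (a nonspecific transient effect; an optional 15% dip,
`early_dip`, is off by default and exists only to exercise the filter).

What the generator does **not** emulate: sex- and study-level baseline
shifts, ADA titres, inter-occasion variability, correlated random
effects, or PD values below a quantification limit (none are
modelled). Passing recovery tests on these data therefore show the
estimation machinery is consistent under the stated statistical
assumptions — not that the original animal data would yield the same
estimates.

## Estimation

`fit_pk()`/`fit_pd()` maximise the Gaussian likelihood implied by the
residual model (`neg2_loglik()`), with positive parameters optimised on
the log scale and bioavailability on the logit scale (Nelder-Mead with
simplex re-inflation, optional `nlminb` polish). PK-PD fitting is
sequential, as in the source analysis: the PK model is frozen, each
subject's concentration course is computed once, and only the PD
parameters move. The fixed-parameter mask mirrors the staged strategy
in which the TMDD block was estimated on low-dose data and then frozen.

Full FOCE-I is deliberately not re-implemented. Three modes cover the
package's needs:

* `pooled` — naive-pooled typical-value fit;
* `two-stage` — per-subject fits summarised by the median. Under
  lognormal BSV the median individual parameter *is* the typical value,
  so this is the package's recommended mode for typical-value recovery;
  the naive-pooled estimate of CL is biased ~25% low under the full
  published BSV, because a population-average concentration curve
  decays more slowly than the typical curve.
* `laplace` — marginal likelihood with diagonal $\omega$ fixed at the
  supplied CVs, random effects integrated out by the Laplace
  approximation. Accurate but expensive; used at small scale.

BLQ observations are excluded (the M1 method), matching the
">LLOQ" construction of the source dataset.

Two further choices matter for PD fitting. Predose cell counts enter
the fit only through the `BL` column (their average) — keeping them as
observations too would anchor the fit on residuals that are zero by
construction. And because `BL` is itself a noisy average (log-scale SD
$\approx \sqrt{\sigma^2_{prop}/3}$ for a three-sample predose run-in),
treating it as exact biases pooled structural estimates: in simulation
the B-cell $C_{50}$ came out ~25% high. `fit_pd()` therefore profiles
one multiplicative baseline factor per animal — a penalised 1-D profile
with the predose-average error as its shrinkage prior, the pooled-mode
analogue of the baseline random effect in the source analysis
(`baseline_scale = FALSE` disables it; the bias then returns, which is
itself informative about the workflow).

### Parameter-recovery experiments

`recovery_design()` fixes the three simulation-study templates used by
the acceptance script and tests: a 40-animal single-dose 3 mg/kg PK
study (15 samples over 42 days), a 30-animal B-cell study
(0.3/3/30 mg/kg dosed weekly for 13 weeks, dense sampling over the
first week then weekly) and a 30-animal NK study (0.1/1/30 mg/kg single
dose, dense sampling for 28 days). All dose after three predose
samples, so the recorded baseline column is a three-sample average —
with a single predose sample the 29–54% proportional residual noise
would propagate straight into $K_{OUT} = K_{IN}/BL$. The B design's
first-dose transient is what identifies MTT: with only weekly samples
the nadir delay falls between samples and a zero-delay model becomes
likelihood-equivalent. PK recovery
uses the full published BSV and combined residual error and refits the
disposition block (CL, VC, Q, VP) in two-stage mode with TMDD fixed; PD
recovery generates at the published typical values with proportional
residual error and baseline heterogeneity from the population sampler,
and refits pooled. Problem sizes (20 PK replicates, 10 PD replicates)
keep each experiment in the minutes range while leaving the replicate
medians stable.

## Noncompartmental analysis

`nca_summary()` follows standard single-dose conventions, since the
source's NCA settings are unstated: linear-up/log-down AUC, $\lambda_z$
by log-linear regression over the best-adjusted-$R^2$ window among the
last 3–6 quantifiable points, $AUC_\infty = AUC_{last} +
C_{last}/\lambda_z$, $CL = \text{dose}/AUC_\infty$,
$V_z = CL/\lambda_z$. On the typical monkey model the results fall
inside all three published single-dose ranges ($V_z$ 64–116 mL/kg, CL
6.04–14.7 mL/kg/day, $t_{1/2}$ 4.75–11.2 days).

## Monkey-to-human scaling and FIH simulation

`scale_params()` applies $P_h = P_m (BW_h/BW_m)^b$ with the standard
monoclonal-antibody exponents — 1.0 for volumes, 0.85 for clearances —
and reference weights 3 and 70 kg. The source relegates its exact
scaling choices to unpublished supplementary material, so these
defaults are explicit assumptions and fully config-exposed. Absorption,
bioavailability and the target-binding block are carried over
unchanged (conservative: no human CD38 turnover data), and human PD
baselines default to the monkey typical values — percent-of-baseline
outputs are insensitive to that choice for T cells and only weakly
sensitive for NK/B through $K_{OUT} = K_{IN}/BL$.

`simulate_fih()` produces single-dose human profiles (2-hour IV
infusion or SC) with per-cell-type nadir, time-to-nadir and 50%
recovery summaries. Two qualitative behaviours the tests pin down: the
0.0003 mg/kg floor dose yields a Cmax far below the 0.05 µg/mL assay
limit (robust to the exponent choice, since Cmax ≈ dose/$V_C$), and SC
dosing depletes less and later than IV at the same dose. The published
human nadir percentages depend on the unpublished supplementary scaling
choices and are treated as qualitative cross-checks only.

```{r fih}
human <- scale_params(monkey_pk_typical())
simulate_fih(0.3, "IV", pk = human, horizon = 56)$summary
```

## Numerical choices and degenerate inputs

* QSS root: evaluated in a cancellation-safe rationalised form; returns
  0 at zero total drug; clamped to $[0, C_{tot}]$.
* ODE tolerances: $10^{-8}/10^{-10}$ (PK) and $10^{-8}/10^{-8}$ (PD)
  for simulation; fitting relaxes to $10^{-6}$ relative (and
  $10^{-4}$ absolute for cell counts of order $10^2$–$10^3$), which
  changes trajectories by under $10^{-4}$ relative while roughly
  halving runtime.
* During fitting, PD predictions are floored at $10^{-6}$ cells/µL so
  the proportional variance stays positive when a trajectory touches
  zero; observed predose averages that are non-positive (possible after
  flooring of noise draws) fall back to the latent baseline in the
  generator, and `fit_pd()` refuses non-positive baselines outright.
* Terminal-slope fitting treats an essentially exact log-linear fit as
  adjusted $R^2 = 1$ and breaks ties toward more points.
* `lambda_z` degenerates to the one-compartment $CL/V_C$ when $Q = 0$.

## Known limitations

* No FOCE-I; standard errors come from a finite-difference Hessian on
  the transformed scale and are approximate.
* The ADA onset model and the per-study sampling clocks are invented
  (flag-and-exclude behaviour is what matters downstream).
* C50 of the NK model is weakly identified from low-dose-only designs —
  the package reproduces this caveat of the original analysis as a
  likelihood-width test rather than hiding it.
* The objective-function value of the original fit is not reproducible
  without the original animal data and is not a target of any test.
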