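# lymphodep

Population PK-PD modelling of lymphocyte depletion by a cytolytic
anti-CD38 monoclonal antibody in cynomolgus monkeys, and model-based
first-in-human (FIH) dose projection.

Anti-CD38 antibodies deplete CD38-expressing blood cells — NK cells most
strongly, B and T lymphocytes to a lesser degree. Before dosing humans,
the dose–exposure–depletion relationship has to be quantified in the
monkey, the only cross-reactive preclinical species. `lymphodep` is
aimed at pharmacometricians working on that problem: it implements the
full model chain as R functions and makes every stage testable without
any proprietary animal data by shipping a calibrated synthetic-trial
generator.

## What is in the package

**PK** — two-compartment disposition with SC depot and target-mediated
drug disposition under the quasi-steady-state (QSS) approximation. The
free concentration solves

    C + Rtot * C / (KSS + C) = Ctot

and the state equations (amounts `depot`, `cen`, `per`; total target
`rtot`) are

    d depot/dt = -KA * depot
    d cen/dt   =  KA * depot + rate - CL*C - Q*(C - Cp) - KINT*RC*VC
    d per/dt   =  Q * (C - Cp)
    d rtot/dt  =  KSYN - KDEG * rtot - (KINT - KDEG) * RC

with `RC = rtot*C/(KSS + C)`. Typical monkey values (e.g. CL 0.0187
L/day, VC 0.141 L, KSS 5.68 ug/mL) are built in as
`monkey_pk_typical()`.

**PD** — three cell-type models driven by the free concentration:
an NK turnover model `dNK/dt = KIN - KOUT*NK - NK*EMAX*c/(C50+c)` with
`KOUT = KIN/BL`; a four-transit-compartment B-cell model with common
rate `4/MTT`; and a direct T-cell response
`T(c) = BL*(1 - EMAX*c/(c + C50))`.

**Around the models** — trial simulation with lognormal between-subject
variability and combined residual error (`simulate_trial()`), the eight
published monkey study templates and a synthetic dataset generator with
ADA flagging (`generate_study_dataset()`), a NONMEM-flavoured CSV
dataset dialect (`read_dataset()`/`write_dataset()`), flag-and-exclude
data cleaning (`exclude_flagged()`), maximum-likelihood estimation in
pooled / two-stage / Laplace modes (`fit_pk()`, `fit_pd()`),
noncompartmental analysis (`nca_summary()`), and allometric
monkey-to-human scaling plus FIH simulation (`scale_params()`,
`simulate_fih()`).

## A worked example

Simulate a typical 3-kg monkey given 3 mg/kg IV, then summarise the
exposure noncompartmentally:

```r
library(lymphodep)
p <- monkey_pk_typical()
times <- c(0.021, 0.25, 1, 3, 7, 14, 21, 28, 42)
prof <- simulate_pk(p, dose_events(0, 9), times)
round(prof$cfree, 2)
#> [1] 54.62 44.45 29.89 22.65 17.13 10.54  6.46  3.94  1.44
nca_summary(prof$time, prof$cfree, dose = 9, body_weight = 3)
#>       Cmax  Tmax AUC_last  AUC_inf   lambda_z   t_half         CL        Vz
#> 1 54.62441 0.021 393.8708 414.0775 0.07141589 9.705784 0.02173506 0.3043449
#>   CL_mL_kg_day Vz_mL_kg
#> 1     7.245021 101.4483
```

The free concentration starts near dose/VC (63.8 ug/mL total, less
after target binding), declines with a terminal half-life of ~10.3 days
(`terminal_halflife(p$CL, p$VC, p$Q, p$VP)` gives 10.27; the sparse-grid
NCA estimate is 9.7), and the NCA clearance (7.2 mL/kg/day) and terminal
volume (101 mL/kg) land inside the published single-dose monkey ranges
(6.04-14.7 and 64-116).

Depletion after the same dose, and the human floor-dose projection:

```r
nk_simulate(pd_typical("NK"), simulate_pk(p, dose_events(0, 9),
            seq(0, 42, 0.1)), c(1, 7, 28))$pct_baseline
#> [1]  8.616646 11.348669 28.156567
max(simulate_fih(0.0003, "IV", pk = scale_params(p))$pk$cfree)
#> [1] 0.002459044
```

NK cells fall to ~9% of baseline within a day and are still depressed
at four weeks; a 0.0003 mg/kg human dose never exceeds 0.0025 ug/mL,
far below the 0.05 ug/mL assay quantification limit — the rationale for
an ultra-low FIH starting dose.

## Layout

```
R/                  model, simulation, estimation, NCA, scaling code
src/models.c        compiled ODE right-hand sides (deSolve interface)
tests/testthat/     unit, property and end-to-end suites
scripts/acceptance.R   reproduction script (see above)
vignettes/          methods vignette: model derivations and choices
```
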