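# rutinpk

Population pharmacokinetics of rutin and of its circulating quercetin
conjugates in rats, after intravenous or oral dosing of the pure flavonoid
or of a *Physalis peruviana* calyx extract.

The package is written for pharmacometricians and PK scientists who want a
fully scripted, testable version of this analysis: structural models,
population submodels, trial simulation, non-compartmental analysis (NCA),
SAEM estimation and visual predictive checks (VPC), with every stage
exercised on synthetic cohorts that emulate the original 50-rat design.

## The models

**Intravenous rutin** follows a two-compartment model with first-order
elimination,

    dX1/dt = k21·X2 − (k12 + k)·X1,   dX2/dt = k12·X1 − k21·X2,

with C = X1/V. The extract matrix acts as a categorical covariate (GEXT)
shifting logit(V) and log(k); random effects on V and k are correlated
(−0.701); the residual error is combined, SD = a + b·f.

**Oral quercetin conjugates** (measured as quercetin after deconjugation)
follow the same disposition with *double-site absorption*: a fraction F1 of
the dose is absorbed at rate ka1 from t = 0, the rest at rate ka2 starting
at t = Tlag2 — the delayed second site reproduces the double-peak typical
of enterically recirculated flavonoid conjugates. Dose group (reference:
100 mg/kg pure rutin) shifts ka1, Tlag2, V and k.

Individual parameters follow `h(P_i) = h(P_pop) + β_level + η_i` with
log/logit transforms and `η ~ N(0, Ω)`. NCA covers trapezoidal
AUC/AUMC with log-linear tails, automatic terminal-slope selection, Cl,
Vdss/Vdz, MRT, Cmax/Tmax and relative bioavailability
`Frel = (AUC_test/AUC_ref)·(D_ref/D_test)`.

## Worked example

```r
library(rutinpk)

# simulate the published design: 10 groups x 5 rats, LLOQ 100 ng/mL
study <- simulate_study(default_design(), pop_model_iv(), pop_model_oral(),
                        seed = 1)

# per-rat NCA and the extract's relative bioavailability
res <- nca_study(study)
sm <- nca_group_summary(res)
auc <- function(g) sm$mean[sm$group == g & sm$parameter == "AUC0_INF"]
relative_bioavailability(auc(10), 14.8, auc(3), 75)

# refit the intravenous population model by SAEM
fit <- saem_fit(study, nca_informed_init(study, "iv"),
                saem_control(restarts = 3, seed = 101))
unlist(fit$model$fixed)
```

This prints (numbers from the run above):

```
> relative_bioavailability(auc(10), 14.8, auc(3), 75)
[1] 20.75833
> unlist(fit$model$fixed)
          V           k         k12         k21
 0.06585481  1.39340382  1.77670225 12.51102316
```

The Frel value is the fold-increase in dose-normalised conjugate exposure
produced by the extract matrix at the highest dose — this particular
synthetic cohort drew a high-exposure 1000 mg/kg group, so its Frel (20.8)
sits above the published group-mean value of 11.2, while the 500 and
750 mg/kg groups (8.8, 7.6; see `analysis/02_nca.R`) bracket theirs. The
recovered intravenous fixed effects sit near the generating values
(V 0.0646 L/kg, k 1.47 1/h), with the distribution constants k12/k21 only
loosely determined — exactly the pattern of the original analysis.

The `analysis/` directory holds the full numbered workflow
(`01_simulate_study.R` … `05_vpc.R`); each step reads and writes plain CSV
under `results/`.

## Package layout

| Area | Files |
| --- | --- |
| Structural models | `R/structural.R` (closed forms + ODE route) |
| Population model | `R/population.R`, `R/transforms.R` |
| Trial simulation | `R/design.R`, `R/simulate_study.R` |
| NCA | `R/nca.R` |
| SAEM, likelihood, SEs | `R/saem.R`, `R/loglik.R`, `R/recovery.R` |
| Diagnostics, VPC | `R/diagnostics.R`, `R/vpc.R`, `R/tables.R` |
| Dataset I/O | `R/io.R` |

The methods vignette (`vignettes/poppk-methods.Rmd`) documents the model
assumptions, estimator internals, numerical choices and known limitations.
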