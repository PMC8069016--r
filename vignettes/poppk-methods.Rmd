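---
title: "Population pharmacokinetics of rutin and its quercetin conjugates: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Population pharmacokinetics of rutin and its quercetin conjugates: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The scientific problem

Rutin (quercetin-3-O-rutinoside) given intravenously to rats is eliminated
within hours; given orally — as the pure compound or as a hydroalcoholic
extract of *Physalis peruviana* calyces — it is not absorbed intact but
circulates as the conjugates quercetin-3-O-glucuronide and
quercetin-3-O-sulfate, measured as quercetin after enzymatic deconjugation.
Two features dominate the data: the plant-extract matrix changes the
kinetics of both the parent and the conjugates in a dose-dependent way, and
the oral curves show a *double peak*, interpreted as a second absorption
site fed by enteric recirculation of effluxed conjugates.

`rutinpk` implements the complete quantitative workflow around these data:
structural concentration models, covariate and random-effects population
submodels, a synthetic trial generator at the published design, per-animal
non-compartmental analysis (NCA), SAEM population estimation with
likelihood, Wald and residual diagnostics, and visual predictive checks
(VPC). Because the package is exercised on synthetic cohorts generated from
the final published models, every stage is testable end-to-end without the
animal data.

## Structural models

**Intravenous bolus, two compartments.** With amounts $X_1$ (central) and
$X_2$ (peripheral),

$$\frac{dX_1}{dt} = k_{21}X_2 - (k_{12}+k)X_1, \qquad
  \frac{dX_2}{dt} = k_{12}X_1 - k_{21}X_2,$$

with $X_1(0)$ equal to the dose and concentration $C = X_1/V$. Units are
fixed package-wide: dose mg/kg, $V$ L/kg, rate constants 1/h, concentration
ng/mL (conversion factor 1000 from mg/L).

**Oral, double-site absorption.** A fraction $F_1$ of the absorbable dose
enters a first depot at $t=0$ and drains at rate $k_{a1}$; the remaining
$1-F_1$ enters a second depot at $t = T_{lag2}$ and drains at rate
$k_{a2}$; both feed the same two-compartment disposition system. The
delayed second site is what produces the double peak. The published
equations write the second-site inflow with an on/off indicator
$\delta_{t \ge T_{lag2}}$ and omit explicit depot amounts; we implement the
standard interpretation — two first-order depot compartments, the second
initialised at the lag time — which matches the stated two-site topology.
For first-order absorption a lagged depot and a dose-splitting event are
output-equivalent, so no claim is made about the original software's
internal machinery.

**Solution method.** Both models have exact poly-exponential solutions
(`macro_constants()` exposes the hybrid rate constants $\alpha \ge \beta$
with $\alpha+\beta = k+k_{12}+k_{21}$, $\alpha\beta = k_{21}k$). The
simulators default to the closed form, evaluated piecewise across the lag
so the derivative discontinuity is handled exactly; a stiff-capable ODE
route (`deSolve::lsoda`, rtol $10^{-8}$, atol $10^{-10}$, event at
$T_{lag2}$) is retained behind `method = "ode"` and the two are tested to
agree below $10^{-6}$ relative. Estimation uses the closed form because the
SAEM chain evaluates millions of profiles. Removable singularities of the
absorption terms (e.g. $k_a \to \alpha$) are nudged by $10^{-7}$ relative,
far below every tolerance used.

## Population model

Individual parameters follow
$h(P_i) = h(P_{pop}) + \beta_{c(i)} + \eta_i$, where $h$ is $\log$ for
rates and volumes and $\mathrm{logit}$ for quantities in $(0,1)$, $c(i)$ is
the individual's covariate level, and $\eta_i \sim N(0, \Omega)$. Two
conventions are inherited from the final published models and kept as-is:

* the intravenous central volume is logit-transformed (its population value
  0.0646 L/kg lies inside the unit interval; the transform is guarded by an
  explicit validity check), and
* random effects exist only for $V, k$ (intravenous; correlated, the
  published correlation is $-0.701$) and $k_{a1}, k_{a2}, F_1, V$ (oral,
  independent). The oral covariate equations print $\eta$ terms also for
  $T_{lag2}$ and $k$, but the fitted-parameter table reports no such
  variability; the table, being the authoritative description of the final
  model, wins.

Covariates are one categorical axis per route: study source (pure rutin as
reference vs. extract, GEXT) for the intravenous model; dose group for the
oral model with 100 mg/kg pure rutin as reference (D75, D500, D750, D1000
carry coefficients on $k_{a1}$, $T_{lag2}$, $V$, $k$). Reference levels have
$\beta \equiv 0$.

**Residual error.** The published models use a "combined" error with
components $a$ (ng/mL) and $b$; the formula is not printed, so we adopt the
default of the software family used for the original fits,
$y = f + (a + bf)\,\varepsilon$, and provide
$\sqrt{a^2+b^2f^2}$ ("combined2"), pure additive and pure proportional
forms as configurable alternatives — the latter two mainly so that
error-model selection by AIC can be demonstrated.

## The synthetic study generator

`default_design()` reproduces the trial: 10 groups × 5 rats; pure rutin
1.45 and 2.9 mg/kg i.v., 75 and 100 mg/kg p.o.; extract 250/500/1000 mg/kg
i.v. and 500/750/1000 mg/kg p.o., dosed in the models as rutin equivalents
(extract dose × 0.0148, from a measured content of 14.8 µg rutin per mg of
extract). Sampling uses the published 14-point schedules per route — the
oral schedule keeps the printed 0.30 h time verbatim, even though it sits
oddly close to 0.25 h — and the assay's lower limit of quantification of
100 ng/mL.

`simulate_study()` draws each rat's random effects, simulates its profile
at the scheduled times, adds combined residual noise and flags values below
the LLOQ as BLQ. BLQ records are *emitted*, not dropped, so downstream
policies stay testable; the pre-dose $t=0$ record is always BLQ. The
generator emulates the study design and the fitted stochastic model — it
does not emulate body-weight variation, assay drift, deconjugation
efficiency or sample handling, so passing tests speak to the estimation
machinery under the declared model, not to robustness against real-world
assay artefacts.

A consequence worth noting: with the published intravenous parameters the
noise-free 1.45 mg/kg profile is 141 ng/mL at 4 h and 12 ng/mL at 6 h, so
quantifiable signal disappears *after* the 4 h sample — the 4 h record
itself sits just above the limit.

## Non-compartmental analysis

Linear trapezoidal integration throughout (the mode used for the original
tables). Terminal slope $\lambda_z$: log-linear least squares over suffixes
of strictly post-Cmax positive points (Cmax excluded, at least three
points), choosing the best adjusted $r^2$ and breaking ties toward more
points — the convention of standard NCA tools, since the original software
names no rule. `AUC_{0\text{-}\infty} = AUC_{0\text{-}last} +
C_{last}/\lambda_z$; the first-moment tail is
$C_{last}(t_{last}/\lambda_z + 1/\lambda_z^2)$; $MRT = AUMC/AUC$;
$Cl = 1000\,D/AUC_{0\text{-}\infty}$ (apparent $Cl/F$ after oral dosing);
$V_{dz} = Cl/\lambda_z$; $V_{dss} = Cl \cdot MRT$ (intravenous only).
Cmax/Tmax are the global maximum, deliberately so for double-peaked
profiles. BLQ records before the first quantifiable point enter as zero;
embedded and trailing BLQ are excluded. The extrapolated AUC fraction is
reported and flagged above 20%.

Relative bioavailability is the dose-normalised AUC ratio; the reference is
an explicit argument, defaulting to the lowest-dose pure-compound group —
the choice that reproduces the published fold-changes (7.9 and 11.2 for the
500 and 1000 mg/kg extract groups) from the printed group means.

## SAEM estimation

`saem_fit()` maximises the marginal likelihood by stochastic approximation
EM:

* **Simulation step.** Per iteration and subject, Metropolis–Hastings on
  $\eta_i$: an independent proposal from the current prior, a *joint*
  adaptive random walk along the empirical covariance of the $\eta$'s
  (coordinated moves matter on the correlated $V$–$k$ ridge), and
  componentwise random walks with acceptance-targeted scales. All kernels
  are vectorised across subjects.
* **Stochastic approximation.** Step size 1 during burn-in (default 250
  iterations), then $1/t^{0.65}$ during smoothing (default 150).
* **M-step.** Fixed effects and covariate coefficients of parameters with
  random effects have closed-form pooled-regression updates from the
  smoothed sufficient statistics; $\Omega$ from the smoothed second
  moments (off-diagonals only where the model declares a correlation).
* **Parameters without variability** ($k_{12}, k_{21}$; oral also
  $T_{lag2}, k$ and their covariate coefficients) receive an *artificial
  random effect* during burn-in whose SD anneals from 0.3 to $5\times
  10^{-3}$, so they share the closed-form update and are explored per
  subject; in the smoothing phase the artificial variability is removed and
  they are polished by a damped warm-started BFGS step. Without this, the
  weakly identified distribution constants drift toward a one-compartment
  collapse before the error model tightens.
* **Stabilisers.** The residual components stay frozen at their initial
  values for the first ~50 iterations (early misfit must load on the
  annealed random effects, not inflate $a$), are damped afterwards, and the
  $\Omega$ diagonal carries a slowly decaying annealing floor against
  shrinkage collapse.
* **Multi-start.** `restarts > 1` runs independent SAEM chains (later ones
  jitter the starting fixed effects, SD 0.4 on the transformed scale),
  keeps the best importance-sampled log-likelihood, and finishes with a
  warm-started polish run. The oral model — 30 estimated quantities and an
  absorption/elimination flip-flop ambiguity — gets 6 restarts in the
  recovery experiments; the 11-quantity intravenous model gets 3.

The log-likelihood is computed by importance sampling (default 1000 draws
per subject) around the conditional modes with a Laplace-based Gaussian
proposal; an adaptive Gauss–Hermite route is available for up to two random
effects and is used in the tests as a deterministic cross-check against a
brute-force grid integration. AIC is $-2\log L + 2\,p$ with $p$ counting
fixed effects, covariate coefficients, random-effect SDs, correlations and
error components. Standard errors come from a finite-difference Hessian of
the importance-sampled likelihood with common random numbers; RSEs of
transformed quantities are mapped by the delta method. When a fit sits on
a weakly identified ridge the observed information can have flat or
non-concave directions; their eigenvalues are clipped relative to the
leading curvature so the resulting huge variances cannot contaminate the
well-determined quantities. Any estimated quantity can be held at its
starting value via `saem_control(fix = ...)`, giving free/fixed control
over the specification.

**BLQ policy.** The default excludes BLQ records from the likelihood; a
censored treatment (integrating the Gaussian mass below the LLOQ) is
available via `saem_control(blq = "censored")`. On these designs the two
give similar recovery, and the exclusion default keeps the baseline
comparable to common practice when the original handling is unreported.

**Starting values** are data-driven (`nca_informed_init()`): NCA clearance
and first-sample back-extrapolation for the intravenous volume; for the
oral route, apparent clearance from NCA, a 1/h elimination scale, and the
second-site delay from the rebound time (the interior minimum after 0.5 h
of the reference group's mean profile, falling back to the median sampling
time when no trough is visible). Covariate coefficients start at zero,
random-effect SDs at 0.3, error components at a fifth of the LLOQ and 15%.

## Visual predictive check

`vpc()` simulates replicate studies (1000 by default) under a model and
design, and per dose group and scheduled time reports the 5th/50th/95th
percentile bands next to the observed percentiles, plus the fraction of
quantifiable observations inside the 90% band. The calibration test runs
on self-simulated data generated *without* LLOQ censoring: censoring
truncates the observed distribution but not the simulated bands, which
would push the coverage fraction up for reasons unrelated to model
adequacy.

## Sizes used by the test-suite experiments

All experiment sizes are the package's own choices: parameter recovery runs
five seeded replicates per route at the full published design size (25 rats
per route); error-model selection uses three seeded intravenous replicates
with shortened SAEM phases (150 + 80 iterations); the VPC calibration uses
1000 replicate studies; the likelihood oracle uses a two-subject toy with a
single random effect where grid integration is exact; the bootstrap SE
sanity check uses five subject-resampled refits.

## Known limitations

* The distribution rate constants $k_{12}, k_{21}$ are weakly identified by
  the intravenous design (first sample at 3 min versus a distribution
  half-life of ~2.5 min); their RSEs are large — as they were in the
  original fits (42% and 32%) — and their point estimates scatter widely
  across replicates. The recovery claims are therefore restricted to the
  well-identified quantities.
* The additive error component $a$ tends to be recovered above its
  generating value on intravenous replicates; it trades off against the
  steep early profile segment and the $V$–$k$ ridge.
* Population values of parameters whose information comes from a single
  five-rat reference group (notably $k_{a1}$) carry maximum-likelihood
  sampling scatter of roughly 10–25% at this design; individual replicates
  can land outside a ±20% band even when the estimator finds the global
  optimum.
* The real study's AIC values and SE columns depend on the animal
  observations and are not reproduced; internal-consistency checks stand in
  for them.
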