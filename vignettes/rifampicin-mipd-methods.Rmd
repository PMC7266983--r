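---
title: "Methods: simulating precision dosing of high-dose rifampicin under inter-occasion variability"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating precision dosing of high-dose rifampicin under inter-occasion variability}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rifmipd)
```

## The problem

Rifampicin, the backbone of first-line tuberculosis treatment, combines
three pharmacokinetic complications that defeat naive dose titration:
auto-induction of its own elimination (exposure falls roughly 45% from
day 1 to steady state), a more-than-proportional increase of exposure
with dose (saturable first-pass loss and saturable elimination), and a
between-occasion ("inter-occasion") random variability in exposure as
large as the between-patient variability. Classical therapeutic drug
monitoring compares one measured exposure to a target; when the same
patient's AUC can differ nearly three-fold between visits purely at
random, that comparison chases noise. Model-informed precision dosing
(MIPD) instead conditions a population PK model on each patient's sparse
concentrations, estimates the patient's random effects, and forecasts the
dose whose *typical-occasion* exposure hits the target.

`rifmipd` implements the full simulation machinery needed to study this
workflow: the structural PK model, a virtual-cohort generator, maximum a
posteriori (MAP) estimation of individual and per-occasion random
effects, the iterative dose-forecasting algorithm, and the summary
metrics.

## Structural model

One disposition compartment with amount $A_c$, an absorption compartment
$A_a$, and a relative enzyme pool $E$ (1 = uninduced):

$$
\begin{aligned}
\dot A_a &= \mathrm{in}(t) - k_a A_a, \\
\dot A_c &= k_a A_a - \frac{V_{max}\,E}{k_m + C_p}\,C_p,
  \qquad C_p = A_c / V,\\
\dot E   &= k_{ENZ}\Bigl(1 + \frac{E_{max} C_p}{EC_{50} + C_p}\Bigr)
            - k_{ENZ} E .
\end{aligned}
$$

Absorption is a transit-compartment chain evaluated in closed form, which
is the only definition available for the estimated non-integer
compartment number ($NN = 23.8$):

$$
\mathrm{in}(t) = F \cdot D \cdot k_{tr}
\frac{(k_{tr} t)^{NN} e^{-k_{tr} t}}{\Gamma(NN + 1)},
\qquad k_{tr} = \frac{NN + 1}{MTT},
$$

superposed over doses. Relative bioavailability rises with dose above
450 mg, $F = F_{450}\,(1 + F_{max}(D - 450)/(ED_{50} + D - 450))$, with
$F_{450} = 1$ fixed below 450 mg for lack of data. Clearance-type and
volume-type parameters are referenced to 70 kg and scaled by fat-free
mass with exponents 0.75 ($V_{max}$) and 1 ($V$); the units of the
published estimates (mg/h/70 kg, L/70 kg) fix the reference size, and the
exponents are the standard allometric pair. Both are fields of
`rif_params()` so alternatives can be explored. Two further augmented
states accumulate $\int C_p\,dt$ (AUC is read off the solution, never
re-quadratured) and eliminated mass (used by the mass-balance tests).

Random effects are log-normal: six IIV etas ($V_{max}, k_m, V, k_a, MTT,
NN$; the single correlation is $V_{max}$–$k_m$) and four occasion (IOV)
etas ($k_m, k_a, MTT, F$) drawn fresh per sampling visit. Reported
percent variabilities are read as $100\,\omega$ on the log scale.
Residual error is additive on the log scale; concentrations below the
quantification limit enter the likelihood through the M3
cumulative-probability term.

### Occasion convention

A sampling occasion is a clinic visit. Occasion etas govern the 24-h
dosing interval of their visit day; intervals between visits run at
typical (zero) occasion deviations. The pre-dose sample, drawn 5 min
before the visit's dose, therefore sits at the tail of the *previous*
interval. The same convention is used for simulation and estimation, so
the estimator is never mis-specified relative to its own data. With this
convention the day-1 pre-dose sample is drug-free and the later pre-dose
troughs are frequently censored (the model's post-induction half-life is
short, typical day-14 trough 0.045 mg/L), which makes the M3 handling
load-bearing rather than decorative.

## Numerical engine

The right-hand side is smooth except at dose times and occasion-day
boundaries, and only mildly stiff (the fastest state rate constant is
$k_a \approx 1.8\,h^{-1}$; the enzyme pool is slow). The integrator is a
compiled adaptive Dormand–Prince 5(4) pair with hard restarts at dose
events and eta-switch boundaries, written for this model so that the MAP
objective — which is evaluated on the order of $10^6$ times in a cohort
run — is a single C call. Default tolerances are rtol $10^{-8}$ / atol
$10^{-10}$ for reference simulations; MAP estimation uses rtol $10^{-5}$
/ atol $10^{-7}$, which changes estimated etas by under $10^{-3}$
(verified against tight-tolerance fits) at roughly a third of the cost.
The compiled solution is cross-checked in the test suite against
`deSolve::lsoda` run on the plain-R right-hand side to $10^{-5}$
relative accuracy, and single-dose mass balance closes to 0.1%.

## Virtual cohort

Sex is Bernoulli (71.1% male). Body weight is truncated normal per sex
(male: mean 55.8, SD 7.4, range 40.7–74.0 kg; female: mean 53.8, SD
10.7, range 40.2–84.2 kg) — the published moments of the study
population, used directly as the location/scale of a range-truncated
normal because the empirical distribution itself is not published. The
asymmetric truncation shifts the realised female mean about +2 kg above
the location parameter; this approximation shifts mode statistics (which
dose is the cohort's most common true dose) but not the variability or
accuracy metrics appreciably. Fat-free mass follows the sex-specific
power functions of weight. Sampling is sparse — 5 min pre-dose, 2 h and
4 h post-dose at visits on days 1, 7 and 14 — and the quantification
limit defaults to 0.3 mg/L (not published; a typical LC-MS/MS figure).

## MAP estimation

The `-2 log` posterior of the packed eta vector (6 IIV + 4 per observed
occasion; the IOV components are dropped when the estimation model is
the re-estimated variant with IOV fixed to zero) is minimised with
bounded L-BFGS-B (±5 prior SDs, objective tolerance $10^{-6}$, forward
finite-difference gradients). Initialisation mirrors the
best-of-many-candidates strategy: the objective is evaluated at
`n_starts = 100` candidates (zeros, the previous cycle's estimate, and
draws from the prior) and full optimisations run from the zero start
plus the best-scoring candidate. Always optimising from zeros makes the
returned minimum monotone in the candidate-set size. Spot checks against
8-start, tight-tolerance reference fits reproduce objectives to four
decimals and identical dose selections.

Two identifiability facts matter for interpreting EBEs. First, the
transit-compartment number has an essentially flat likelihood even under
15-min sampling of the absorption phase, so its eta is prior-dominated
by construction; recovery tests therefore assert exact recovery for the
five identifiable etas only. Second, with three samples per occasion the
EBEs are strongly shrunk — that is the phenomenon under study, not a
defect: dose forecasts from a single occasion are barely better than
forecasting from covariates alone, and the value of the second occasion
is precisely the headline result.

## Dosing algorithm

The day-1 dose is 35 mg/kg rounded to the 300-mg tablet grid (nearest
multiple, exact ties down, floor 600 mg; the trial's weight bands are
not published). After each occasion, AUC$_{0-24h}$ at the next target
day is forecast for every grid dose 600–3,300 mg — simulated as given
once daily from day 1, with the subject's IIV EBEs and all occasion etas
zeroed — and compared with the time-varying acceptable range (342–408 on
day 1 falling to 181–214 at steady state, tracking induction). The
lowest in-range dose wins; if none is in range, the closest, ties to the
lower dose. Forecast targets are day-matched to the next scheduled
visit; the reference "true dose" uses each subject's true IIV etas at
the day-14 range, which the induction-consistent construction of the
target table makes comparable across forecast days (in the
perfect-information limit the pipeline reproduces the true dose exactly
for every subject — a test).

## What the experiments show, and problem sizes

`experiment_iov_typical()` (1,000 occasions, IOV etas only, typical
patient at 1,800 mg, steady state taken as day 25 — exposures change
< 1% per day past day 24) and `experiment_iiv_population()` (1,000
patients, IIV etas only) quantify the two variability components on the
AUC scale with the divisor-$N$ log-scale SD and order-statistic 95%
prediction intervals. The IIV experiment deliberately isolates the
random etas: all patients share the typical covariates and the fixed
1,800-mg reference dose, exactly parallel to the IOV experiment's
design; an option samples covariates and doses per kilogram instead,
which adds weight-driven spread (~28% instead of ~24%) on top of the
random component and is useful for population-level questions but not
for quantifying IIV itself. `experiment_population_exposure()` contrasts
day-14 exposure distributions with and without occasion etas on shared
subjects. The MIPD experiments run 200-subject cohorts in the
test suite and a 400-subject cohort in the reproduction script (the
full-size study uses 1,000); at 200 the overall accuracy metrics move
by roughly ±1.5 percentage points across seeds, at 400 by about ±1.

The generator emulates the study conditions, not reality in full: no
dropout or non-adherence, no assay-batch effects, a parametric weight
distribution in place of the unpublished empirical one, and occasion
etas attached to visit-day intervals only. Conclusions about *relative*
performance (with vs without IOV in the model; one vs two vs three
occasions) are insensitive to these simplifications; absolute per-dose
stratified statistics, and especially which dose is the cohort's mode,
are not.

## Known limitations

* The enzyme-turnover equations and allometric details are reconstructed
  from the published parameter table and model lineage; the
  reconstruction reproduces the published typical-exposure trajectory
  (day 1/7/14 AUC inside the published target ranges) but is not
  guaranteed identical in unobserved regimes.
* The per-subject exact-hit rate at the cohort's modal true dose is
  65–70%, consistent with the published per-dose imprecision at the mode
  (a miss there is at least one tablet step, and rRMSE ≈ 10.5% implies
  ~28% misses); the often-quoted "95%" can only be read as
  distribution-level agreement of the forecast and true dose histograms,
  which this package reproduces within ~5%.
* Bootstrap difference CIs use the percentile method (B = 2,000 by
  default); the CI construction behind the published significance flags
  is not specified in detail.
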