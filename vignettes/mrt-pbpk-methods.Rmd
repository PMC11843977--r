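---
title: "Methods: a whole-body PBPK model for antibodies in the male reproductive tract"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a whole-body PBPK model for antibodies in the male reproductive tract}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mrtpbpk)
```

## The model

`mrtpbpk` simulates the disposition of a non-target-binding IgG (a
150 kDa monoclonal antibody) in a whole-body physiological network
extended with mechanistic sub-models of the five male reproductive
organs. The state vector holds antibody *amounts* (nmol) in every
sub-compartment; concentrations are derived at reporting time by
dividing by sub-compartment volumes. Storing amounts rather than
concentrations keeps the stiffness of tiny sub-compartments (the vas
deferens endosome is 2e-8 L) out of the state scaling.

Each of the 15 platform organs has five states: vascular plasma,
vascular blood cells, endosomal unbound, endosomal FcRn-bound, and
interstitial. Organs are perfused in parallel from the lung; the
spleen, pancreas and intestines drain through the liver; interstitial
lymph from every organ collects in a lymph-node pool that returns to
plasma. Vascular-to-interstitial transport is convective,
`(1 - sigma_v) L C_V`, with the lymph flow `L` fixed at 1/200 of the
organ plasma flow. Endosomal uptake is fluid-phase pinocytosis from
both the vascular and interstitial sides, `CLup * V_E * C`, with the
endosomal volume `V_E` fixed at 0.5% of the organ volume. In the
endosome the antibody binds FcRn at a fixed free-receptor
concentration; unbound antibody is degraded at `kdeg`; bound antibody
exits at the pinocytosis rate, a fraction `FR` recycling to the side it
came from and `1 - FR` crossing the cell.

Because free FcRn is held constant — the standard assumption for
tracer-dose IgG far below FcRn capacity — every flux is linear in the
state and the whole model is `dx/dt = A x` for a constant Metzler
matrix `A`. Two auxiliary states accumulate the only two sinks
(endosomal degradation and luminal excretion), so
`dose = remaining + degraded + excreted` can be audited at any time;
the test suite holds this to 1e-6 relative and better.

### The male reproductive organs

The five MRT organs add, on top of the platform organ structure:

* an **epithelial barrier compartment** — the blood-testis barrier
  (BTB) in the testis, the blood-epididymal barrier (BEB) in the
  epididymis, and the epithelial lining of the vas deferens, seminal
  vesicle and prostate gland. Mechanistically this compartment is the
  *endosomal space of the barrier cells*: antibody is pinocytosed into
  it from the interstitium, binds FcRn there, and the non-recycled
  fraction is released into the lumen.
* a **luminal space** fed by the epithelium and flushed by seminal
  fluid along the chain testis lumen → rete testis → epididymis → vas
  deferens → seminal vesicle → prostate gland → out of the body, with
  per-organ flows `Q_retetestis, Q_ep, Q_vd, Q_sv, Q_pg`.
* a **muscular transit layer** in the three accessory glands, modelled
  as a well-mixed compartment between interstitium and epithelium that
  exchanges with both at the pinocytosis rate scaled by the muscular
  volume. Setting `muscular_transit = FALSE` collapses it to a
  pass-through (the epithelium then exchanges directly with the
  interstitium); the layer itself is retained in the tissue
  reconstruction either way.
* in the testis, the **rete testis**, a single well-mixed transit
  compartment between the testis lumen and the epididymis lumen.

The testis BTB uses its own fitted pinocytosis rate (`CLup_BTB`) and a
ten-fold lower FcRn concentration than the endothelium; the testis
endothelium uses its own fitted rate (`CLup_E_testis`); all other MRT
epithelia share the platform endothelial `CLup` and FcRn.

### Design choices where the source equations were ambiguous

The printed compartment equations this model descends from contain
several transcription artifacts (duplicated uptake terms, an epithelial
uptake written from the vascular space while the text describes uptake
from the interstitium, a rete-testis influx proportional to the rete's
own concentration). The right-hand side here is therefore written from
flux consistency — every efflux term appears as an influx in exactly
one other compartment — and verified by the global mass-balance audit
rather than transcribed line by line. Three choices deserve explicit
record:

1. **The paracellular luminal leak is driven by the epithelial
   concentration.** Each MRT lumen receives, besides pinocytotic
   delivery, a lymph-like leak `(1 - sigma_ep) L C_ep`. Driving this
   term by the *interstitial* concentration instead would let antibody
   bypass the barrier entirely, and in the testis — whose lumen drains
   only through the minuscule rete-testis flow — it accumulates until
   the testis ABC exceeds reported values by an order of magnitude.
   The epithelial reading is also what the source lumen equation
   literally states.

2. **The barrier compartment volume is endosomal.** Pinocytosis rates
   are defined per litre of endosomal volume, so the kinetic volume of
   each epithelial barrier is 0.5% of the anatomical barrier layer —
   the same rule the platform applies to whole organs. The exception is
   the epididymis, whose effective barrier volume was itself an
   estimated parameter (`BEB_volume`, default 2.8e-4 L) and is used as
   supplied. With the full anatomical epithelium as kinetic volume the
   packaged parameter estimates drive an implausible fraction of the
   dose into the dead-end testis lumen; with the endosomal reading the
   same estimates put the simulated testis ABC in the reported ~2%
   regime. Tissue reconstruction keeps the full anatomical layer volume
   in the homogenate denominator either way.

3. **The testis lumen drains by bulk flow.** The testis lumen-to-rete
   and rete-to-epididymis transfers both use `Q_retetestis`, the only
   flow assigned to this path; a pinocytotic transfer would need a
   clearance the source never defines. Since `Q_retetestis` is
   essentially zero (its reported CV% is 283 — the data cannot identify
   it), the testis lumen is in effect a slow accumulation compartment,
   and testis exposure is insensitive to this flow, as the sensitivity
   analysis confirms.

Other recorded assumptions: vascular volumes are split into plasma and
blood cells at a hematocrit of 0.45 (the ratio of the two printed flow
columns confirms this split); lymph does not carry luminal content;
the antibody molecular weight (150 kDa) and body weights (mouse
0.028 kg, rat 0.25 kg, monkey 6.2 kg, human 71 kg) are defaults exposed
in `dose_event()` and `load_species_physiology()`.

## Parameters

The MRT physiology tables (flows in L/min, volumes in L, converted to
canonical L/h and L on ingestion) and the eight estimated MRT
parameters ship with the package:

```{r}
load_mrt_parameters()
```

The platform-organ physiology and the global antibody/FcRn kinetics are
**not** part of the source tables; the packaged files
(`platform_physiology_mouse_synthetic.csv`,
`global_kinetics_platform_synthetic.csv`) are a synthetic
representative set assembled for this package from standard rodent
physiology and canonical IgG/FcRn kinetics: `kon = 8.06e7 /M/h`,
`koff = 6.55 /h`, endothelial FcRn `4.98e-5 M` (the BTB value,
`4.98e-6 M`, is anchored by the stated ten-fold reduction),
`kdeg = 26.6 /h`, `FR = 0.715`, `CLup = 0.55 L/h/L`. Reflection
coefficients default to `sigma_v = 0.95` (0.99 for brain),
`sigma_IS = 0.2`, and `sigma_ep = 0.95` for the epithelial leak, the
last being a modelling default since no source value exists. These
choices give IgG-like whole-body kinetics (plasma half-life of a few
days at tracer dose); absolute tissue AUC predictions inherit their
uncertainty and are **not** reference values — which is why the
packaged printed AUC table, not a simulation, backs the worked-example
metrics. Everything is overridable through the parameter-file
interfaces.

## Estimation

Observed datasets are tidy `(tissue, time_h, conc_nM, replicate)`
tables. The study this package emulates sampled destructively (one
measurement per animal), so the likelihood is naive-pooled — every
record independent, no inter-animal random effects — which is a
deliberate methodological simplification relative to population
approaches. The residual model is combined additive-proportional,
`SD(t) = delta_intercept + delta_slope * Y(t)`. Fitting maximizes the
Gaussian likelihood by L-BFGS-B on log-parameters (positivity by
construction; box bounds default to three decades around the initial
values); standard errors come from the finite-difference observed
information in log space, mapped back by the delta method, so
`CV% = 100 * SE_log` and Wald intervals respect positivity. Staged
plans are supported and mirror the source workflow: barrier parameters
(`CLup_BTB`, `CLup_E_testis`, `BEB_volume`) first, then the luminal
flows with the barrier fixed.

`Q_retetestis` is structurally near-unidentifiable under the study
design (its flux is orders of magnitude below anything the data
resolve); requesting it in a fit triggers a warning rather than an
error. `Q_ep` is weakly identified in this implementation: the
epididymis signal is dominated by its barrier compartment, so the
luminal contribution that carries the `Q_ep` information is small, and
its confidence intervals are accordingly wide.

## The synthetic-data generator

`generate_dataset()` emulates the biodistribution study design: plasma
sampled at 5 min, 6, 24, 96 and 168 h; the five MRT tissues at 6, 24,
96 and 168 h after whole-body perfusion (vascular content zeroed in the
reconstruction, volumes retained in the denominator); three animals per
time point; a single 10 mg/kg IV bolus. Noise is drawn once per record
from the combined error model and truncated at zero — truncation, not
resampling, which biases records near the noise floor slightly upward;
at study-scale noise (`delta_intercept = 0.1 nmol/L`,
`delta_slope = 0.2` — *test settings chosen for this package; the
source never reports its fitted residual parameters*) fewer than 0.5%
of records are affected, and the realized fraction is attached to every
dataset. One seeded generator per dataset; the caller's RNG state is
saved and restored.

What the generator does **not** emulate: inter-animal physiological
variability (all replicates share one body), assay censoring (no
LLOQ/ULOQ), and any model misspecification — synthetic data are drawn
from the same model that is later fitted. Passing recovery tests
therefore demonstrates the correctness of the estimation machinery and
the identifiability structure of the design, not the model's fidelity
to real tissue data.

## Numerical choices

* **Integration.** Default back-end `lsoda` (deSolve) with the analytic
  constant Jacobian, `rtol = 1e-8`, `atol = 1e-10`. Because the system
  is linear and time-invariant, a second back-end propagates it exactly
  with matrix exponentials (`Matrix::expm`, scaling-and-squaring): when
  all report-time gaps are integer multiples of the smallest gap, one
  base exponential is squared dyadically and each step costs a few
  matrix-vector products. The two back-ends agree to 1e-6 relative and
  better; estimation and sensitivity use the exact path (one likelihood
  evaluation ~30 ms for the 124-state mouse model), solver-tolerance
  studies use `lsoda`.
* **Dosing.** IV boluses are state jumps at event times with the
  integration restarted, never smoothed inputs.
* **AUC.** Linear trapezoid from the first to the last node, no
  extrapolation; sensitivity and ABC computations use a 0.5 h grid over
  0–168 h (337 nodes), at which the trapezoid error is far below the
  2% comparisons made on it. A log-trapezoid variant exists behind a
  flag and is not the default.
* **Degenerate inputs.** Zero dose yields the zero trajectory; zero
  total reconstruction volume, empty datasets, non-increasing grids and
  unknown organs raise typed errors; non-finite predictions during
  fitting return a penalized objective with a diagnostic attribute so
  the optimizer can back away.
* **Problem sizes in the shipped checks.** The recovery study fits the
  five-parameter identifiable subset (`Q_ep, Q_vd, Q_sv, Q_pg,
  CLup_BTB`) to 20 synthetic study replicates (75 records each) and
  evaluates joint Wald-interval coverage; the sensitivity analysis runs
  8 parameters × 2 directions on the 0.5 h grid. These sizes keep the
  full suite in a few minutes on one CPU while leaving the Monte-Carlo
  error of the coverage estimate (binomial, n = 100) well inside the
  0.90 acceptance margin.

## Known limitations

* No target-mediated disposition, no FcRn saturation or competition
  with endogenous IgG, no subcutaneous or intratesticular routes.
* The platform parameter set is a labelled synthetic stand-in;
  simulated absolute exposures should be read as illustrative until a
  user supplies a validated platform parameterization.
* Cross-species MRT predictions rest on printed species tables that
  contain visible anomalies (an implausibly large human testis
  epithelial volume, a seminal-vesicle blood-cell flow exceeding its
  plasma flow); the validator surfaces these as warnings and the values
  are used as printed.
* The naive-pooled likelihood understates uncertainty relative to a
  population analysis when real inter-animal variability is present.
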