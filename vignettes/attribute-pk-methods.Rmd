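---
title: "Methods: modeling quality-attribute pharmacokinetics from isotope-calibrated peptide quantitation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: modeling quality-attribute pharmacokinetics from isotope-calibrated peptide quantitation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(attrpk)
```

## The measurement model

The pipeline starts where instrument software stops: a long-format table
of integrated XIC peak areas per `(subject, time, peptide, modification
form)`, split into *light* areas (peptides from circulating drug) and
*heavy* areas (the same peptides from a ¹³C/¹⁵N-labeled internal
calibrant spiked at a fixed amount into every serum aliquot). Two
quantities come out of this table:

* **Relative attribute level** — the modified form's share of all forms
  of its reporter peptide, `area(mod) / Σ area(forms)`. Ionization
  efficiency cancels within a peptide, so this needs no calibrant.
* **Absolute concentration** — the light/heavy ratio times the known
  calibrant amount over the serum volume. With the default protocol
  (2.5 µg calibrant in 12.5 µL serum) a ratio of 1 corresponds to
  200 µg/mL. The calibrant travels through affinity purification,
  digestion and LC-MS together with the analyte, which is what makes this
  conversion bias-free.

Total drug concentration is the unweighted mean of per-peptide
concentrations over a reference panel (default 20 peptides) chosen by the
two stated criteria — high intensity, and absence of carryover and
modifications. We operationalize these as: exclude any peptide with a
modified form anywhere in the table, exclude any peptide with a nonzero
pre-dose light area (carryover), rank the rest by median light intensity
across all samples, break ties lexicographically. Whether the panel mean
should be weighted is not specified anywhere we know of; we use the
unweighted mean, which keeps the estimator's noise behaviour transparent
(CV shrinks ~√20-fold relative to a single peptide).

Missing data are flagged, never imputed: an all-zero denominator (the
pre-bleed) yields `NA` for a fraction, a zero heavy area yields `NA` for
a concentration, and light/heavy ratios below a configurable floor
(default 1e-4) are flagged `below_lloq` but retained. A time point loses
its total-concentration value only if more than half the panel is
missing, and is then flagged.

## The mechanistic model

Each attribute is modeled independently (attribute interactions are
deliberately out of scope): the drug is split into *original* and
*modified* forms, each following a standard two-compartment disposition
with shared distribution rates, and coupled by first-order conversion:

$$
\begin{aligned}
\dot A_{C0} &= -(k_{CP}+k_{tr}+k_{cl0})A_{C0}+k_{PC}A_{P0}\\
\dot A_{P0} &= -(k_{PC}+k_{tr})A_{P0}+k_{CP}A_{C0}\\
\dot A_{Cmod} &= -(k_{CP}+k_{clmod})A_{Cmod}+k_{tr}A_{C0}+k_{PC}A_{Pmod}\\
\dot A_{Pmod} &= -k_{PC}A_{Pmod}+k_{tr}A_{P0}+k_{CP}A_{Cmod}
\end{aligned}
$$

with $A_{C0}(0)=(1-f)\,\mathrm{Dose}$, $A_{Cmod}(0)=f\,\mathrm{Dose}$,
zero peripheral amounts, and central concentrations $C = A_C/V$. Note the
$k_{tr}A_{P0}$ term: conversion operates in the peripheral compartment
too, exactly as the model is stated; we implement it verbatim rather than
taking a position on whether tissue-phase conversion is physiological.

Two constraint sets encode the biological assumptions:

| kind | constraint | rationale |
|---|---|---|
| deamidation-like | $k_{clmod}=k_{cl0}$ | conversion chemistry is the driver; deamidation does not alter clearance |
| man5-like | $k_{tr}=0$ | glycoforms are set intracellularly and do not form in circulation |

Both kinds share $k_{CP},k_{PC}$ between forms. All rates are in d⁻¹
(days are the internal time unit throughout; hour-based AUC reporting is
an explicit ×24 at the boundary), $V$ in litres, dose in mg — which makes
amounts/volume come out in µg/mL numerically.

Two closed forms follow from the structure and serve as independent
oracles everywhere in the test suite:

* **Equal clearance** ⇒ the central modified fraction is
  $1-(1-f)e^{-k_{tr}t}$, independent of distribution and clearance. With
  $k_{tr}=0.01$ d⁻¹ and $f=0$, day 42 gives 0.343.
* **No conversion** ⇒ each form is an ordinary two-compartment bolus
  model; `biexp_coefficients()` gives the eigen-rates
  $\lambda_{1,2}=\frac{(a+b)\pm\sqrt{(a+b)^2-4bk_{cl}}}{2}$ (with
  $a=k_{CP}+k_{cl}$, $b=k_{PC}$) and amplitudes $A=(λ_1-k_{PC})/(λ_1-λ_2)$,
  $B=1-A$ of the central unit-bolus biexponential.

## Numerics

`simulate_attribute()` integrates with `deSolve::lsoda` at rtol 1e-8 /
atol 1e-12·Dose. Because the system is linear and time-invariant, an
exact spectral route (eigen-decomposition of the 4×4 rate matrix) is also
available and is what the fitting objective uses — it is two orders of
magnitude faster and agrees with the integrator to better than 1e-6
relative error (asserted in the tests). The spectral route checks its own
reconstruction error and falls back to the integrator when the rate
matrix is near-defective (coincident eigenvalues), which can occur at
contrived parameter ties; `biexp_coefficients()` likewise flags a
repeated eigen-rate as degenerate rather than returning amplitudes.

AUCs are computed by augmenting the ODE state with cumulative integrals
of $C_0$ and $C_{mod}$ (rtol 1e-10), not by quadrature on a sampled
grid — windowed exposures are therefore grid-independent. Relative AUC,
$100\cdot\mathrm{AUC}_{mod}/\mathrm{AUC}_{total}$, is invariant to dose,
$V$ and any concentration scale; absolute AUCs are reported per unit
dose unless anchored by `calibrate_scale()`, which fixes the single
multiplicative scale from one known total exposure (the absolute dose
behind published exposure tables is typically not knowable from the
table itself, so the anchor is the honest route to absolute values).

## Estimation

`fit_attribute()` maximizes a Gaussian likelihood on two observable
series jointly: total central concentration (proportional error) and
attribute fraction (additive error). This pairing matches what the
measurement stage actually produces; fitting the two forms' separate
concentrations would presume a decomposition the data do not directly
give. Two deliberate choices:

* **Fixed error scales.** `sigma_prop` (default 0.10) and `sigma_add`
  (default 0.02) are dataset attributes, not estimated. Profiling them
  out drives the objective to −∞ on noise-free data; fixed scales keep
  the objective finite and only reweight the two data blocks.
* **Observation-anchored proportional weights.** The concentration term
  uses `sd = sigma_prop × observation` (the classical 1/y² weighting)
  rather than `sigma_prop × prediction`. With prediction-anchored
  weights the fixed-σ likelihood has its optimum displaced from the
  truth by O(σ²) even on noise-free data (the `log σμ` term rewards
  shrinking predictions); observation anchoring makes the zero-noise
  optimum sit exactly at the generating parameters, which the tests
  require to 0.1%.

Free parameters (the unconstrained rates and $V$) are optimized in log
space, which enforces positivity without constraints. The search is a
seeded multi-start (default 20 starts: one heuristic centre with rates at
0.1 d⁻¹ and $V$ from the earliest post-dose concentration, the rest
lognormally dispersed with sd 0.7 on the log scale) of Nelder-Mead
followed by a BFGS polish of the best start. `f` is *not* estimated: the
initial modified fraction of the administered batch is a release
measurement, an observable, and the pre-dose serum sample cannot inform
it (it contains no drug). The dose is likewise held at its known value,
which is what identifies $V$ (otherwise only Dose/V enters).

Parameter CVs come from the inverse observed information (numerical
Hessian of the NLL at the optimum, in log space; the log-scale SD is to
first order the relative SD, reported as percent). A parametric
bootstrap (`bootstrap_cv()`) is available as a cross-check and is
asserted to agree within a factor of 2 on synthetic data. Constrained
parameters carry no CV of their own.

## What the synthetic generator emulates — and what it does not

`study_config()` defaults encode the emulated study: 3 subjects, one IV
bolus, 11 sampling times (pre-bleed, 10 min, 1 h, 4 h, 12 h, days 2 and
4, weeks 1, 2, 3 and 6), a 2.5 µg heavy calibrant in 12.5 µL serum, and
10% proportional peak-area noise. Four default attributes span the
qualitative behaviours of interest: deamidation rising from 5.6% toward
~38% by day 42, Man5 falling from 3% to ~0.6%, pyroglutamate converting
96% → ~99.9% (a fast deamidation-like model, `ktr = 0.1` d⁻¹), and a
mildly declining Met oxidation 8.5% → ~6.7% (a man5-like model with
`kclmod = 0.148` d⁻¹, chosen once to give the small downward trend).
The default dose is a unit bolus: every acceptance-grade quantity is a
dose-invariant ratio, and absolute scales are reachable through
`calibrate_scale()`.

Design decisions the generator takes a position on:

* **Noise model.** Multiplicative lognormal with unit mean on *light*
  areas. Heavy areas are noise-free: the calibrant spike is a constant,
  and placing the measurement noise on the drug-derived signal makes the
  CV of the light/heavy ratio equal the configured `noise_cv` exactly —
  the property the replicate-noise test checks. The error model of any
  real instrument is unknown; this is the simplest model consistent with
  ratio-based quantitation.
* **One total-drug kinetics.** A real study has one drug; this generator
  carries several attribute models at once, whose total-drug solutions
  differ slightly. The clean-peptide (total) signal follows the *first*
  configured attribute's total trajectory; studies built for parameter
  recovery therefore list the fitted attribute first (the test helpers
  do this).
* **Shared parameters across subjects.** Inter-subject variability is
  not part of the model — subjects differ only by independent noise
  realizations, consistent with the observation that attribute dynamics
  are similar across patients. Consequently, passing recovery tests says
  nothing about mixed-effects designs.
* **Calibrant purity** is modeled as exactly 100% (real heavy labels are
  ~99%); a purity correction would be a constant multiplier absorbed by
  the calibration anchor anyway.
* **Pre-bleed.** The time-0 sample precedes the bolus and carries zero
  drug signal; downstream stages must (and do) tolerate all-zero light
  areas.

What passing the synthetic suite does **not** show about real data:
peak integration, retention-time drift, interference and charge-state
deconvolution all live upstream of this pipeline's entry point; the
generator emulates none of them (it emits already-merged areas —
`merge_charge_states()` is exercised on constructed per-charge tables).

## Problem sizes and reproducibility

The test suite and the acceptance script regenerate everything from
code: no stored fixtures. Parameter-recovery checks run the full
generate → quantify → fit chain at the clinical design (11 × 3 points,
10% noise) for 5 replicates per attribute model with 8 optimizer starts
each — the pooled median relative error is a stable statistic at this
size, and the noise-free consistency check (truth recovered to ≤0.1%)
covers the asymptote. Exposure-table reproduction uses the reference
parameter sets directly and is deterministic. One seed drives a run:
`generate_study()` seeds from the config, `run_pipeline()` derives
per-stage seeds from it by fixed offsets, so a rerun is byte-identical
(asserted on the CSV outputs).

The deamidation relative-AUC reproduction lands ~0.2–0.3 percentage
points below the published table values; that offset is what propagating
two-significant-figure rate constants produces, and the tolerance used
(±0.5 pp; ±0.2 pp for the Man5 model) reflects exactly that rounding,
not a fudge factor.

## Known limitations

* Linear PK only: no target-mediated disposition, FcRn recycling or
  nonlinear clearance; single bolus, no infusion duration, no
  multiple-dose or steady-state exposure.
* One attribute at a time; combinatorial variants (a molecule that is
  both deamidated and Man5) are not represented.
* The asymptotic CVs assume a locally quadratic likelihood; for weakly
  identified designs (sparse sampling, high noise) prefer
  `bootstrap_cv()` and expect the factor-of-2 agreement to degrade.
* The interface is R functions plus `run_pipeline()`; there is no shell
  entry point, as the intended users work in R.
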