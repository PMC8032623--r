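---
title: "Methods: PBPK reverse dosimetry and benchmark-dose modeling in revdosim"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: PBPK reverse dosimetry and benchmark-dose modeling in revdosim}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of the science it implements:
the models, their assumptions, the tunable parameters, the numerical
choices, and the limits of what the tests demonstrate.

## The extrapolation problem

Repeated-dose in vitro studies in 3D rat brain-cell aggregates expose the
culture to amiodarone every other day for 14 days and measure (i) the
compound's concentration–time course over 24 h in medium, cells and
plastic on the first and last treatment day, and (ii) choline
acetyltransferase (ChAT) activity, a cholinergic neurotoxicity marker, as
% of control across exposure levels. The question the package answers:
*what human intravenous (and, after conversion, oral) dose produces the
same brain exposure as each in vitro exposure level*, and at what dose
does the translated dose–response predict an adverse shift?

Key concept: because of extensive adsorption to plastic labware and slow,
nearly irreversible cellular accumulation, the *measured intracellular*
exposure differs from the *nominal* medium concentration by orders of
magnitude. The package implements both routes — measured-metric
extrapolation and nominal-concentration extrapolation — precisely so the
difference between them is computable.

## The PBPK model

`pbpk_simulate()` integrates a whole-body model with arterial and venous
blood, a lung compartment, and ten tissues (names are configuration, not
code: brain, heart, liver, kidney, muscle, skin, adipose, gut, spleen,
rest-of-body in the shipped fixtures). Each tissue splits into a vascular
and an extravascular sub-compartment; exchange between them is
permeability-rate-limited:

$$V_{vas}\frac{dC_{vas}}{dt} = Q\,(C_{art}-C_{vas}) -
  PS\,(fu_b C_{vas} - fu_t C_t), \qquad
  V_t\frac{dC_t}{dt} = PS\,(fu_b C_{vas} - fu_t C_t)$$

with $fu_b = fu_{plasma} / R_{b:p}$ the unbound fraction referred to
whole blood. Only the liver eliminates, at the constant-clearance rate
$CL \cdot fu_t \cdot C_t$ applied to the unbound extravascular liver
concentration. Venous blood collects all tissue outflows plus the i.v.
input; the circulation closes through the lung (also
permeability-limited) into arterial blood. Assumptions: linear kinetics
throughout (no saturable binding or metabolism), well-stirred
sub-compartments, instantaneous bolus mixing into venous blood.

Numerical choices: the state vector is integrated in *amounts* (mg), so
mass balance is available at solver precision; `deSolve::lsoda`
(stiff-capable) with rtol 1e-8, atol 1e-10; output grid 0.05 h by default
(0.1 h in the reverse-dosimetry configuration — the day-14 24-h AUC of
the slowly-equilibrating brain compartment is insensitive to this).
Boluses are instantaneous state increments at the dose times (solver
events); infusions are zero-order input terms with events marking the
on/off discontinuities so the solver restarts there. A zero dose is a
valid input and returns identically zero profiles; non-finite states
abort with the failure time; negative round-off below 1e-8 of the dose is
clamped to zero.

Because clearance is constant, the system is *linear in dose*: profiles
scale proportionally and multiple doses superpose. The test suite checks
conservation (relative error ≤ 1e-3), linearity and superposition
(≤ 0.5%), and the one-compartment closed form
$C(t) = (D/V)e^{-(CL/V)t}$ in a degenerate parameterization. One design
note on that oracle: elimination acts on the *extravascular* liver
concentration, so a parameterization with literally all PS = 0 cannot
eliminate at all; the test instead takes the PS → ∞ limit for the liver
(huge PS, unit unbound fractions, negligible tissue volume, very large
cardiac output), which reduces the model to the same closed form.

## Parameter fixtures

The shipped YAML fixtures (`pbpk_human.yaml`, `pbpk_rat.yaml`) are
**synthetic, representative parameterizations**, documented as such in
their headers: standard reference physiology (73 kg human: cardiac output
390 L/h, tissue volumes and flows from reference tables; 250 g rat scaled
accordingly) with literature-style compound parameters for a highly
protein-bound lipophilic drug (fu_plasma = 0.06, blood:plasma ratio 0.73,
MW 645.31 g/mol). The brain PS product (3.2e-4 L/h) is a **calibration
constant**: it is fixed so that the simulated day-14 brain extravascular
AUC per unit dose reproduces published amiodarone reverse-dosimetry dose
scaling (measured exposure targets of 1.00 and 1.99 µg·h/mL map to a few
mg/kg). It should be read as "the fixture reproduces the published
exposure-to-dose slope", not as a measured blood–brain-barrier
permeability. All acceptance checks that depend on the fixture are
documented as fixture-calibration checks.

## Kinetic metrics and the dosing-regimen mapping

In vitro metrics are computed from the *mean* profile over replicates
(mean first, then metric), by linear trapezoid for AUC with endpoint
interpolation but **no extrapolation** beyond the first/last observation,
and by the sampled maximum for Cmax. Per-flask amounts are converted to
µg/mL with the medium volume (medium) or lysate volume (cells); the
lysate volume has no default and must ship with the dataset.

The human regimen used for the day-14 metric is **daily** i.v. bolus
dosing for 14 days, with the metric window at hours 312–336 (the 24 h
after the 14th dose). The in vitro schedule was every-other-day; the
in vivo mapping is a deliberate, configurable choice
(`revdose_config(n_doses =, interval =)`) — daily dosing matches how the
drug is used clinically, and the published dose scale this package's
fixture is calibrated to is consistent with that reading. Likewise the
brain "intracellular" concentration is taken to be the whole
extravascular sub-compartment concentration; this is an assumption, not a
derivation.

## Reverse dosimetry

The defining contract is a brute-force scan: candidate doses are
multiples of 0.01 mg (total mg, not mg/kg) in [0.01, 2000] mg, and the
selected dose minimizes |predicted − measured| metric, ties broken toward
the smaller dose; an optimum at the scan boundary raises a warning. The
default `method = "linear"` exploits dose-linearity: simulate once at a
reference dose, scale analytically to a candidate grid dose, then verify
by simulating the candidate and both grid neighbours. `method = "scan"`
simulates every grid dose and exists as the oracle; the acceptance suite
checks the two agree to within one grid step across parameter
perturbations and target sizes. mg/kg values divide by the fixture body
weight (73 kg).

## Benchmark-dose analysis

`bmd_fit()` fits four continuous, decreasing families, all of the form
$f(x) = a\,g(x;b,d,c)$ with $g(0)=1$:

* exp3: $a\,e^{-bx^d}$, exp5: $a(c + (1-c)e^{-bx^d})$
* hill3: $a(1 - x^d/(b^d+x^d))$, hill5: $a(1 - (1-c)x^d/(b^d+x^d))$

The likelihood assumes normal residuals with a common σ and is built from
group summary data (mean, SD, n): with
$SS = \sum_i [(n_i-1)s_i^2 + n_i(\bar y_i - f_i)^2]$ and $N = \sum n_i$,
the profile log-likelihood is $-\tfrac N2(\log(2\pi SS/N)+1)$. Two
analytic profiling steps keep the optimization small and reliable: σ is
profiled out as above, and the background $a$ has the closed-form
optimum $\hat a = \sum n_i \bar y_i g_i / \sum n_i g_i^2$. The remaining
shape parameters are optimized by `nlminb` on log/logit scales with box
bounds ($d \in [0.25, 15]$, $c$ via logit in ±12) from a deterministic
lattice of 10 starts (potency × shape grid plus four spread starts);
best likelihood wins, ties to the first found. Doses are internally
rescaled by the maximum dose, making the fit exactly equivariant under
rescaling of the dose axis.

The reported residual SD is the degrees-of-freedom-corrected estimator
$\hat\sigma = \sqrt{SS/(N-k)}$ ($k$ = curve parameters); the ML variance
$SS/N$ is biased low by $(N-k)/N$, which matters both for the benchmark
response (below) and for parametric bootstrap generation, where simulating
with the ML σ produces systematically too-narrow intervals. Likelihood
and AIC remain ML quantities.

**Goodness of fit** is the likelihood-ratio lack-of-fit test against the
saturated (free group means) model, χ² with (number of groups − number of
curve parameters) degrees of freedom; σ is common to both models and is
not counted. Fits are accepted at *P* > 0.05. With zero df the test is
undefined; such a fit is treated as accepted only if it interpolates the
group means.

**Benchmark response**: BMR = 1 SD of the background response. Which SD
"background" means is genuinely open (control-group sample SD vs model
residual σ); the package defaults to the model's df-corrected residual σ,
with `background_sd` available to override (e.g. with the control-group
SD). The BMD solves $f(0) - f(BMD) = \sigma_{bg}$ by bracketing +
bisection (`uniroot`) to relative tolerance 1e-8, searching up to 10× the
maximum tested dose. A curve that is essentially flat across the tested
range (total in-range drop below 1e-6 of the required drop) returns a
"not reached" signal rather than an extrapolated crossing — with a flat
fit the shape exponent is unidentified and any crossing beyond the data
would be an artifact of it.

**Model averaging**: Akaike weights $w_i \propto e^{-\Delta AIC_i/2}$
over accepted fits; the point BMD is the weight-averaged log-BMD. The 90%
interval is a parametric bootstrap: each replicate draws a generating
model with probability $w_i$, simulates group means
$\mathcal N(\hat f_i, \hat\sigma^2/n_i)$ and SDs from the matching scaled
χ², refits every accepted family (warm-started from the original fit),
and records the replicate's weight-averaged BMD; BMDL/BMDU are the
5th/95th percentiles. Replicate failures are counted (a warning above
20%); the seed is required, and the caller's RNG state is restored.

## The synthetic-data generator

`generate_biokinetics()` emulates the *structure* of the in vitro
biokinetic experiments with a three-pool linear exchange ODE (medium ⇌
cells, medium ⇌ plastic, cells → metabolite) under every-other-day
dosing with full medium renewal (configurable to "add"). Defaults are a
calibration, not ground truth: exchange rates are set so that 14-day
exposure at 1.25–2.5 µM gives day-14 cell AUCs near 1–2 µg·h/mL with
strong plastic adsorption, slow cellular accumulation (day-14 ≫ day-0
exposure) and a metabolite share of cellular drug near 3% — the regime
the extrapolation operates in. Measurement noise is multiplicative
log-normal with a 15% CV by default; five sampling points in [0, 24] h
(including t = 0, so the 0–24 h window is spanned without extrapolation);
three replicates.

What it does *not* emulate: saturable or lysosomal trapping kinetics,
cytotoxicity feedback on kinetics, metabolite kinetics (the metabolite is
a cumulative loss pool only), plate-to-plate variability, or values of
any specific published experiment. Passing tests therefore demonstrate
that the pipeline's *operations* are correct and calibrated on data with
the right structure and scale — not that any real study is reproduced.

`generate_chat_response()` draws group summary statistics around a known
decreasing curve (default exp5 with background 100%), which enables
closed-form-truth recovery studies.

## Study designs used by the test suite

Problem sizes are the package's own choices, balancing statistical
resolution against runtime:

* **Recovery/coverage study**: exp5 truth (a = 100, b = 0.06414, d = 1.5,
  c = 0.55), closed-form BMD* = 1.5 at BMR = 1 SD with SD = 5% of
  control; 6 dose groups (0, 0.5, 1, 2, 4, 8 mg/kg), n = 5 per group;
  200 completed analyses of the full four-family averaging pipeline with
  n_boot = 200. Datasets where no family passes the *P* > 0.05 gate
  (about the gate's own 5% type-I rate under a correctly specified model)
  produce no benchmark dose by construction and are skipped. Checked:
  point-estimate bias within ±10%, interval coverage of BMD* in 85–95%,
  and BMDL ≤ BMD ≤ BMDU in every run.
* **Reverse-dosimetry oracle**: 3 parameter perturbations × 3 targets,
  exhaustive scan restricted to a ±0.05 mg window around the shortcut
  answer (the scan is the contract; the window keeps it affordable).
* **Pipeline runs**: 4–5 exposure levels, n_boot = 200–500.

## Dose conversions and the nominal route

`iv_to_oral()` divides by oral bioavailability (human 0.65, rat 0.35),
`perkg_to_total()` multiplies by body weight (73 kg), and
`free_to_total()` scales a free dose to a total dose using Fu = 0.06.
Two free-dose conventions are implemented: `fraction_standard`
(dose/Fu, dimensionally standard) and `table_printed` (dose × 100/Fu,
the rule used in published amiodarone nominal-concentration tables —
dimensionally irregular, reading Fu as a percentage, but required to
reproduce those printed totals). The conversion routine records which
convention was applied and uses `table_printed` only in the
nominal-concentration reporting path, with a notice attached.

In the pipeline's `metric = "nominal"` mode, the nominal medium
concentration (a free concentration in protein-free medium) is converted
to µg/mL and matched against the simulated *peak venous blood*
concentration; the protein-binding correction is applied once, at the
final oral total. This reading is what makes the published
nominal-route arithmetic internally consistent (the resulting i.v. doses
are roughly nominal concentration × blood volume, far smaller than the
measured-metric doses, while the final ×100/Fu step makes the total far
larger); matching instead against free brain concentration would apply
the binding correction twice.

## Known limitations

* The PBPK fixtures are representative, calibrated parameterizations;
  absolute tissue concentrations outside the calibrated brain-exposure
  slope carry no validated meaning.
* Strictly linear kinetics: no saturation, induction, or time-varying
  clearance; amiodarone's very long terminal phase is not a calibration
  target.
* BMD machinery covers continuous, decreasing, summary-statistic data
  with common normal σ; no quantal endpoints, no covariates, no
  log-normal response option beyond the residual-model hook.
* The gof χ² and the bootstrap are asymptotic/plug-in approximations at
  small n; the coverage study quantifies their joint calibration at the
  study's design size only.
* Oral dosing is a scalar bioavailability conversion, not an absorption
  model; interspecies translation is a parameter swap, not allometry.
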