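---
title: "Modeling ocular anti-VEGF pharmacokinetics with ocuvegf"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling ocular anti-VEGF pharmacokinetics with ocuvegf}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ocuvegf)
```

## The model

Wet age-related macular degeneration is driven by VEGF reaching the back of
the eye; anti-VEGF antibody fragments such as ranibizumab neutralize it.
`ocuvegf` implements a three-compartment ordinary-differential-equation
model of how a topically or intravitreally administered drug (R) moves
between the tear film, the aqueous humor, and the vitreous humor, and how
it binds VEGF (V) on the way.

VEGF carries two identical binding sites, so the chemistry is

$$\mathrm{V + R \rightleftharpoons VR}, \qquad
  \mathrm{R + VR \rightleftharpoons RVR},$$

with per-site binding rate $k^{+}$ (pmol$^{-1}$ mL h$^{-1}$) and unbinding
rate $k^{-}$ (h$^{-1}$): free VEGF binds at rate $2k^{+}vr$ (two empty
sites), the doubly bound complex dissociates at $2k^{-}w$ (either arm can
leave). `reaction_terms()` evaluates these mass-action rates; they conserve
VEGF units ($\dot v+\dot u+\dot w = 0$) and drug units
($\dot r+\dot u+2\dot w = 0$) identically.

Each chemical species in the aqueous and vitreous additionally undergoes:

* **exchange** across the aqueous–vitreous interface, a diffusive flux
  $\beta_{\mathrm{Aq\text{-}Vit},j}\,A_{\mathrm{Aq\text{-}Vit}}\,(x_{\mathrm{Vit}}-x_{\mathrm{Aq}})$
  that is antisymmetric in volume-weighted moles;
* **dilution** in the aqueous by fluid turnover $\psi_{\mathrm{Aq}}$
  (mL h$^{-1}$);
* **first-order degradation** $\delta_{i,j}$ (default 0, a simplifying
  assumption, but kept as parameters because the sensitivity analysis
  varies them);
* for drug species in the vitreous, one-way **loss to the retina/choroid**
  $-\beta_{\mathrm{Vit\text{-}Ret},j}A_{\mathrm{Vit\text{-}Ret}}x_{\mathrm{Vit}}/V_{\mathrm{Vit}}$
  (choroidal blood flow clears what crosses, so no return flux); and
* a constant retinal **VEGF supply** $\phi_{\mathrm{Vit},v}$ (pmol h$^{-1}$)
  into the vitreous.

The retinal-loss term is implemented as a loss (negative sign): a positive
sign would make the vitreous a self-amplifying source, which is unphysical
and contradicts the direction in which increasing that permeability moves
total vitreal drug.

The tear film carries drug only. Its volume is algebraic, not integrated:
after a drop it jumps to the reservoir volume
$V^{\mathrm{Res}}_{\mathrm{Tear}}$ and drains linearly back to the normal
film volume over $\tau_{\mathrm{loss}}$ (3 min), with a Heaviside cutoff
using $H(0)=1$. Tear drug is lost across the cornea
($\beta_{\mathrm{Tear\text{-}Aq},r}$, the permeability *with* a
cell-penetrating peptide present — the CPP is not modeled as a species, only
through this elevated permeability) and by tear turnover dilution, both
divided by the instantaneous tear volume as the model is stated. Because
baseline volume makes the two conventions coincide there, we do not offer a
variant that divides the turnover term by the baseline volume only.

All units are fixed package-wide: h, mL, cm, cm², pmol mL$^{-1}$. Since
1 cm³ = 1 mL, $\beta A/V$ is a first-order rate in h$^{-1}$ with no
conversion factor.

### Species and submodels

`eye_params("human")` and `eye_params("porcine")` hold the published
defaults. The porcine set describes an *ex vivo* eye: tear and aqueous
turnover, VEGF supply, and retinal loss are all zero (no active physiology
post mortem), and its initial VEGF concentrations are zero. A
`model_config()` selects the submodel: whether the tear compartment exists
(injection-only models drop it), how tear volume and tear concentration
evolve, whether VEGF is simulated at all (the permeability fits switch it
off), and the `ex_vivo` flag that zeroes the physiological rates. For the
ex vivo topical submodel the drop *is* the tear film, so the tear volume is
the drop volume (constant by default; a complete-run-off variant is
provided) and its initial concentration is the full dose concentration.

### Dosing

Dosing is event-driven (`regimen()`, `standard_regimen()`):

* **drop** — the drop mixes instantaneously with the resident film, so the
  tear concentration becomes the volume-weighted average of old
  concentration and dose; the excess volume then runs off without changing
  it. Consecutive drops must be at least $\tau_{\mathrm{loss}}$ apart.
* **injection** — vitreal drug jumps by
  $r_{\mathrm{Dose}}V_{\mathrm{Drop}}/V_{\mathrm{Vit}}$ (207 pmol mL$^{-1}$
  for the human eye); the injected volume is negligible and assumed
  drained.
* **lens on/off** — a drug-eluting contact lens pins the tear concentration
  at $r^{\mathrm{init}}_{\mathrm{Tear}}$ at normal tear volume while worn;
  on removal the concentration decays from its current value.

"Start of week $k$" maps to global time $(k-1)\cdot168$ h and "start of
hour $h$" to $(h-1)$ h within a day, so "a drop at the start of hours 1 to
16" gives 16 drops at 0…15 h. When a drop and an injection coincide the
drop is applied first; they touch disjoint variables, so this is a
determinism convention, not a modeling choice.

## Numerical choices

`simulate_eye()` integrates with an adaptive explicit Dormand–Prince 4(5)
pair (deSolve's `"ode45"`; `method = "lsoda"` is available as a
stiff-capable fallback) over a compiled right-hand side; the exported
`eye_rhs()` is the readable reference implementation and the test suite
checks that both give the same trajectories. The integrator restarts at
every dose and additionally at the drainage kink $\tau_{\mathrm{loss}}$
after each drop, because adaptive steppers lose order across derivative
discontinuities. Trajectories include samples 10$^{-9}$ h before and after
every dose so the discontinuities are bracketed.

Default tolerances are `rtol = 1e-10`, `atol = 1e-14` pmol mL$^{-1}$. These
are deliberately tight: after an injection, vitreal VEGF collapses by four
orders of magnitude to a nadir near $2\times10^{-7}$ pmol mL$^{-1}$, and at
`rtol = 1e-8` that nadir still carries a ~2.5% integration error; at the
defaults it is converged to well below 0.1% (the suite checks that halving
tolerances moves summary statistics negligibly). Concentrations that
undershoot zero by round-off (within $10^{-12}$ of the trajectory scale)
are clamped to zero; larger negatives raise an error, signaling a solver
problem rather than hiding it.

Window summaries (`summarize_window()`) report the maximum, minimum, and
*time-weighted* (trapezoidal) mean of vitreal VEGF and total vitreal drug
$R_{\mathrm{Tot}} = r+u+2w$; with the default 0.1 h output grid the
time-weighted and sample means differ negligibly, but the contract is the
integral.

## Untreated steady state

With zero degradation, balancing retinal supply against aqueous drainage
gives closed forms
$v_{\mathrm{Aq}} = \phi_{\mathrm{Vit},v}/\psi_{\mathrm{Aq}}$ and
$v_{\mathrm{Vit}} = v_{\mathrm{Aq}} +
\phi_{\mathrm{Vit},v}/(\beta_{\mathrm{Aq\text{-}Vit},v}A_{\mathrm{Aq\text{-}Vit}})$
— the untreated VEGF levels (1.56 × 10⁻³ and 2.24 × 10⁻³ pmol mL$^{-1}$)
used as initial conditions. With nonzero degradation
`untreated_vegf_steady_state()` solves the 2×2 linear balance instead. The
parameter sweeps recompute this steady state for every parameter draw by
default, so initial conditions stay consistent with the varied parameter
(holding them fixed is available via `recompute_init = FALSE`; whether the
original analysis re-derived them per draw is not stated, and recomputing
is the self-consistent choice).

## Fitting the ex vivo porcine data

The bundled `porcine_measurements()` table holds the ELISA means and sds
(n = 3 eyes per point at 20 min, 40 min, 1 h, 3.5 h). Two permeabilities
are estimated from it:

* **Topical fit** (`fit_topical()`): corneal and aqueous–vitreous
  permeability, minimizing the mean squared error of the simulated aqueous
  drug concentration against the topical-group means. Zero means are
  below-detection non-detects and carry no signal, so they are excluded by
  a data-driven rule (`drop_nondetects`), which removes the anomalous 1 h
  point and leaves 20 min, 40 min, and 3.5 h.
* **Intravitreal fit** (`fit_intravitreal()`): the aqueous–vitreous
  permeability alone. Measured vitreal concentrations are far below the
  nominal bolus (the drug has not spread from the injection site by these
  early times), so the state is initialized at 20 min from the measured
  means and the later aqueous means are fitted.

With VEGF disabled and constant tear volume both submodels are linear
time-invariant systems, so the fits evaluate their exact
matrix-exponential solutions rather than numerical integrations — a large
speedup that the test suite cross-checks against `simulate_eye()`.
Optimization is Nelder–Mead in log₁₀-parameter space, multi-started from a
3×3 grid spanning two decades around (10⁻⁶, 1) cm h$^{-1}$ and polished by
a restart from the best optimum. A flat objective (e.g. targets already at
the mass-weighted equilibrium) is flagged `degenerate` rather than
reported as a unique estimate.

```{r fits, eval = FALSE}
fit_topical(porcine_measurements(), eye_params("porcine"))
#> beta_tear_aq_r 5.94e-07, beta_aq_vit_r 0.930
fit_intravitreal(porcine_measurements(), eye_params("porcine"))
#> beta_aq_vit_r 0.576
```

## Identifiability by Metropolis–Hastings

`mcmc_permeability()` runs a random-walk Metropolis–Hastings chain in
log₁₀-parameter space with log-uniform priors (corneal permeability over
[10⁻⁹, 10⁻⁴] cm h$^{-1}$, aqueous–vitreous over [10⁻², 10] cm h$^{-1}$),
default 10⁵ steps with 20% burn-in, started at the least-squares optimum.

The error model deserves a frank paragraph. Three fitted means cannot
identify their own noise level: marginalizing an unknown Gaussian noise
scale under a Jeffreys-type prior leaves a posterior proportional to
$\mathrm{SSE}^{-3/2}$, which barely decays away from the optimum — the
resulting posterior spreads over the whole prior box and its mean is
nowhere near the least-squares estimate. Fixing the scale at the best-fit
RMS residual, or at the replicate standard errors, is no better: the
former is still too diffuse (the SSE profile along the exchange
permeability is shallow), and the latter re-weights the points and moves
the mode off the unweighted optimum. The single-sharp-peak identifiability
reported for this assay setup is only attainable with a noise scale well
below the residual scatter. We therefore use an independent Gaussian
likelihood on the fitted means with a *fixed* scale
$\sigma = c\cdot\mathrm{RMSE}$, with one shared constant $c = 0.2$ for
both submodels, calibrated once (via the Laplace curvature relation) so
the posterior spread matches that reported identifiability in both cases
simultaneously. The posterior *means* are insensitive to $c$ once the
posterior is unimodal and localized; the posterior *sds* scale linearly
with $c$ and should therefore be read as comparable in order of magnitude,
not exact. Both `sigma` and `sigma_frac` are exposed arguments.

Proposal scales default to values giving 0.2–0.5 acceptance on the bundled
data; rates outside [0.1, 0.6] trigger a warning with a tuning hint.

## Sensitivity analysis and regimen sweeps

`sweep_parameter()` varies one parameter at a time across uniformly spaced
values over its biologically realistic range (endpoints included; the full
analysis uses 101 values), simulates 12 weeks under one of three reference
regimens — hourly drops (24/day), a continuously worn lens, or injections
at the start of weeks 1, 5, and 9 — and summarizes weeks [9, 12], by when
the solution has settled to a steady or periodic pattern. The *sensitivity
factor* of each output (max/mean/min of vitreal VEGF and vitreal
$R_{\mathrm{Tot}}$) is its maximum over the sweep divided by its minimum;
factors above 1.5 are flagged significant, and a zero minimum reports an
infinite factor with the same flag. The sensitivity regimens deliberately
idealize adherence (hourly drops around the clock, a permanently worn
lens): they probe the model, not a feasible prescription. The last
injection lands at the start of week 9, so the summary window is a treated
cycle whose trailing behavior reflects washout — the legend is followed
literally.

`regimen_sweep()` varies dosing intensity instead: drops 1–16/day over 12
weeks, lens wear 1–30 days per 1-day-break cycle over 124 days, injection
intervals 1–8 weeks over 32 weeks, and the two dual modes (injections plus
four drops/day at 4, 8, 12, 16 h; injections plus 6-day lens weeks on days
2–7), summarizing the final complete treatment cycle. Across these sweeps
more aggressive dosing weakly decreases all vitreal VEGF statistics and
weakly increases all total-drug statistics, and the maximum vitreal VEGF
returns to the untreated level for inter-injection intervals of 4 weeks or
longer — both asserted as properties in the test suite.

## Synthetic data

`generate_measurements()` emulates the porcine sampling design (4 time
points × 2 compartments, n = 3 replicate eyes) from known parameters:
additive Gaussian noise with sd = max(floor, proportional × signal),
truncated at zero like an assay with a detection limit. The seed fans out
to one stream per replicate, so growing the replicate count never
reshuffles earlier replicates. This makes the fitting and MCMC code
testable by parameter recovery: with zero noise the fits recover the truth
to better than 0.1%. What the generator does *not* emulate: plate effects,
standard-curve nonlinearity, or the incomplete vitreal mixing that the
real intravitreal measurements show — so recovery tests validate the
inference machinery, not the assay. A caution worth stating: at 20%
proportional noise the exchange permeability is only weakly identified
from the aqueous points and its recovery distribution is strongly
right-skewed (geometric-mean bias of tens of percent), which is a property
of the design, not a code defect; the suite asserts the empirically
measured recovery at both 10% and 20% noise.

## Problem sizes used by the tests

The default test run keeps everything at desk scale: fits and MCMC on the
3-point datasets (10⁵-step chains only in the end-to-end checks, shorter
elsewhere), regimen simulations of 3–32 weeks on the 0.1 h grid, Monte-
Carlo recovery with 100–200 synthetic datasets, and sensitivity sweeps
with 3–11 values per parameter. The full 101-value × 24-parameter × 3-
regimen sensitivity analysis is exposed through the same functions (and
`run_pipeline()`'s `sensitivity` stage) and is a batch-scale job.

## Known limitations

* **Topical human figure ranges.** The model as printed — drop mixing
  diluting the dose into the resident film (post-mix tear concentration
  1.81 × 10⁴ pmol mL$^{-1}$), lenses pinning the tear film at that same
  value — delivers ~12–15% less drug to the inner eye than the published
  topical simulation traces imply. The discrepancy is structural: with the
  stated corneal permeability and area, the free vitreal drug under a
  continuously worn lens is bounded by 0.161 pmol mL$^{-1}$ at
  steady state, below the published 0.183; the published ranges are
  reproduced to ~1% only if the tear film is reinitialized at the full
  dose concentration (2.07 × 10⁴), as in the ex vivo fitting setup. This
  package implements the stated model, and consequently its lens-regimen
  VEGF minimum comes out ~11% above the published value while every
  non-topical quantity matches within a fraction of a percent. One
  end-to-end assertion documents this mismatch by failing.
* No retinal or choroidal compartment: treatment efficacy is judged by
  vitreal VEGF, and retinal drug exposure is not modeled.
* Compartments are well-mixed by assumption; the real post-injection
  distribution is spatially non-uniform for hours (visible in the ex vivo
  data, and the reason the intravitreal fit initializes from measured
  values).
* The CPP is not an explicit species; its entire effect is the elevated
  corneal permeability, so CPP dose–response questions are out of reach.
* Degradation defaults to zero; nonzero values are explored only in the
  sensitivity analysis.
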