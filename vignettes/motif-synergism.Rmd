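---
title: "Quantifying synergism of paired parameter perturbations in signaling motifs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying synergism of paired parameter perturbations in signaling motifs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE, collapse = TRUE, comment = "#>")
```

## The question

Combination therapies work best when two interventions act *synergistically*:
the joint effect exceeds what either intervention achieves alone, or what the
sum of their individual effects predicts.  Whether a given pair of targets can
be synergistic depends on where the targets sit in the regulatory network.
This package asks that question in the cleanest possible setting: small,
deterministic ODE models of recurring three-node signaling motifs, in which
"drugs" are percentage changes of kinetic parameters, and the "clinical
response" is the peak activation of a downstream target.  A two-gene
bistable switch of the transcription factors CREB1 and CREB2 provides a more
biologically grounded companion model.

## The canonical model and its motif extensions

Two upstream elements A and B are activated by a common stimulus `S` and
converge on a target T.  A and B obey first-order ODEs with basal and
stimulus-driven activation and Michaelis–Menten deactivation:

$$\frac{dA}{dt} = k_{basal,A} + k_{sA} S - \frac{k_{dA}\,A}{K_A + A},$$

with the symmetric equation for B.  The target integrates the *saturable
effects* $f_A = A/(K_{TA}+A)$ and $f_B = B/(K_{TB}+B)$ of the two pathways,
either multiplicatively (Variant M, an AND-like gate) or additively
(Variant A, an OR-like gate):

$$\frac{dT}{dt} = k_{basal,T} + k_{ST}\,\mathrm{act}(f_A, f_B)
                  - \frac{k_{dT}\,T}{K_T + T},
\qquad \mathrm{act} = f_A f_B \ \text{or}\ f_A + f_B.$$

The standard values of the 14 parameters (see `standard_params()`) make A
and B activate quickly and deactivate slowly, keep the basal synthesis of T
far below its induced synthesis, and balance the two pathways exactly, so
that `A(t)` and `B(t)` are identical traces.

Nine motif variations are obtained by *regulating the deactivation rates*
`k_dA` and/or `k_dB` from within the motif.  A regulated rate takes one of
two minimal hyperbolic forms in its regulator X (see `regulated_rate()`):

* decreasing (the regulator protects its target): $k\,K/(K+X)$;
* increasing (the regulator promotes deactivation): $k\,X/(K+X)$.

These are the minimal monotone, saturating forms consistent with
Michaelis–Menten kinetics used everywhere else in the model; the constants
of each motif (`motif_catalogue()`) are chosen so the regulated rate is
comparable to the canonical 0.2 min⁻¹ near the resting state (e.g. the
increasing form with k = 0.4, K = 1 equals 0.2 exactly at X = 1, the
canonical resting level).  The catalogue covers a coherent positive and an
incoherent negative feed-forward loop (`p_ffl`, `n_ffl`), mutual excitation
and inhibition between A and B (`me`, `mi`), positive and negative
auto-regulation of A (`auto_pos`, `auto_neg`), a negative feedback loop
between A and B (`nf_ba`), and negative or positive feedback from T onto
both elements (`nf_tab`, `pf_tab`).

Time is in minutes throughout; concentrations are non-dimensional.

## Stimulus, response and the perturbation protocol

The stimulus is a 10-min square pulse of amplitude `S` (1 to 40) rising
from zero, applied to a system resting at its pre-stimulus steady state
(`find_presimulus_steady_state()`; located by long basal integration with a
residual below 1e-9 min⁻¹).  The *response* to a set of parameter changes
is the percentage increase of the peak level of T over the control peak
(`response()`).  Perturbations are chronic: parameters change at t = 0 and
stay changed, which mimics a continuously present drug.

A single *budget* constrains each perturbation experiment: the sum of
absolute percentage changes of the two parameters of a pair is held at 90%
(so rates stay positive and inhibition cannot exceed 90%).  Each parameter
is perturbed in the direction that *increases* the peak of T, determined by
simulation (`determine_direction()`); for example `k_dA` is decreased and
`k_ST` increased.  The allocation grid splits the budget in 30 evenly
spaced fractions from 0 to 1, endpoints included (`allocation_grid()`).

Two curves are built per pair (`blending()`):

* the **NB curve** — the response to the *joint* change at each allocation
  (nonlinear blending);
* the **AE curve** — the *sum* of the two single-parameter responses at the
  same allocations (the additive null model).

The two curves coincide at the endpoints by construction, where one of the
two parameters carries the whole budget.

## Degrees of synergism

With `E = max(NB(0), NB(1))` the maximal single-parameter effect:

* **Strong NB synergism** — the NB maximum beats both endpoints; the degree
  is `max(NB) − E` (in percentage points of response).
* **Weak NB synergism** — concave-down curve whose maximum still sits at an
  endpoint; the degree is defined as 0 (a mixture never beats the best
  single perturbation).
* **NB antagonism** — the curve sags below the straight chord joining its
  endpoints; the degree is the most negative deviation below the chord.

Classification uses only these max/chord comparisons; curvature is never
fitted, so the rules are insensitive to solver noise.  The **degree of
additive synergism** is the signed value of `NB − AE` at the grid point
where `|NB − AE|` is largest.  The sign convention matters: because the
curves agree at the endpoints, an unsigned maximum could never be negative,
whereas an AE curve lying above the NB curve is genuine additive
antagonism and must yield a negative degree.  Both the largest and the most
negative gaps are recorded (`degree_add_max`, `degree_add_min`), since
intertwined curves can display synergism and antagonism simultaneously.  A
degree above 1 is classified additive-synergistic, below 0 antagonistic.

`sweep_all_pairs()` runs this analysis for all 91 unordered pairs of the
14 canonical parameters (28 pairs of the 8 CREB parameters), memoizing the
single-parameter responses that the AE curves share; `count_exceeding()`
and `synergy_histogram()` summarise the tables with strict thresholds and
half-open bins.  `dose_effect_vs_stimulus()` recomputes the degrees across
stimulus amplitudes, and `run_sensitivity_suite()` covers the standard
robustness scenarios (B-pathway parameters jointly reduced by 50/70/90%, a
60-min delay of B's activation implemented as a delayed stimulus seen only
by B, and ±25% changes of each T-dynamics parameter).

## The CREB1/CREB2 switch

The companion model has two state variables: the transcription activator
CREB1 (x) and the repressor CREB2 (y), which bind competitively — as
dimers, like all bZIP factors — to shared CRE sites:

$$\mathrm{occ} = \frac{x^2/K_x}{1 + x^2/K_x + y^2/K_y},\qquad
\frac{dx}{dt} = r_{bas,x} + V_x^{\mathrm{eff}}\,\mathrm{occ} - k_{dx}x,\qquad
\frac{dy}{dt} = r_{bas,y} + V_y\,\mathrm{occ} - k_{dy}y.$$

The quadratic self-activation makes the switch bistable at the standard
parameters: a LOW state (x ≈ 0.09) and a HIGH state (x ≈ 9.5) coexist.
The dimeric occupancy is a deliberate modelling choice: with first-order
occupancy the same parameter values admit only a single attractor, and no
protocol can switch anything.  `K_x` and `K_y` are accordingly dimer–DNA
dissociation constants in squared concentration units.

A standard 5-HT protocol (five 5-min pulses, 20-min gaps) transiently
raises the effective `V_x` from 0.4 to 3.7 min⁻¹ and drives the system from
LOW to HIGH.  When `V_x` itself is perturbed, the elevated value scales
proportionally (9.25-fold): 5-HT is read as a fold-induction of CREB1
synthesis capacity, so a chronic drug that changes `V_x` changes both the
basal and the induced rate.  The response measure is the percentage
increase of the HIGH-state ratio `[CREB1]/[CREB2]` over control
(`creb_response()`), computed after the protocol plus relaxation to a
residual below 1e-9 min⁻¹.  Perturbed runs start from the perturbed
model's own LOW state, again the chronic-drug convention.

## Numerical choices

* **Integrator** — classical fixed-step RK4 (`integrate_rk4()`), step
  0.05 min (3 s), with the stimulus evaluated at the sub-stage times `t`,
  `t + dt/2`, `t + dt`.  Pulses are half-open intervals whose edges are
  multiples of `dt`, so no step straddles an edge ambiguously.  Fourth-order
  convergence is verified in the test suite; an adaptive solver (deSolve)
  serves only as a cross-check there, never as the reference path.
* **Horizon** — 3000 min by default for three-node models.  T's
  deactivation rate (0.01 min⁻¹) makes its dynamics slow, so the peak must
  be bracketed: whenever the peak falls in the final 5% of samples the
  horizon doubles, up to 24000 min.
* **Interstimulus interval** — defined as the gap from pulse offset to the
  next onset (a 20-min gap gives a 25-min period); an onset-to-onset
  reading is available via `interval_semantics` and recorded in the run
  manifest.
* **Ties and degeneracies** — direction ties break toward +1 with a
  warning; parameters with no effect on the response are flagged but still
  enumerated (their blending curves are flat and all degrees are 0);
  failed pairs become flagged rows of the sweep table, not crashes.
* **Tolerances** — steady-state residual 1e-9 min⁻¹; degree classification
  tolerance 1e-6 (so solver-level noise cannot manufacture "strong"
  synergism).

## Limitations worth knowing

* Under the hyperbolic regulated rates, the motifs whose deactivation is
  suppressed by their own activity — mutual excitation, positive
  auto-regulation, and positive feedback from T — have *no finite resting
  state*: the maximal regulated deactivation cannot balance basal
  activation (0.1 min⁻¹), so A and B drift upward indefinitely at rest.  Simulations of these motifs therefore start from
  the resting state of the corresponding unregulated model — the state the
  pathway occupies before the feedback loop engages — and their responses
  depend on the simulation window.  `find_presimulus_steady_state()`
  reports the residual when asked for a fixed point that does not exist.
* The same is true of strong deactivation perturbations in *any* motif: a
  decrease of `k_dA` beyond 50% pushes the basal production of A above the
  Michaelis–Menten deactivation ceiling, so A grows without bound and the
  measured peak is the end-of-window value (the horizon cap).  Degrees
  involving such allocations are finite but window-dependent; the manifest
  records the horizon policy for exactly this reason.
* The models are deterministic and non-spatial; no stochastic simulation,
  no mRNA intermediates in the CREB model, and no bifurcation analysis
  beyond locating the LOW/HIGH attractors.
* Degrees are expressed in percentage points of the response, not
  normalised to the single-drug effect; comparisons across stimulus
  strengths should keep in mind that the control peak itself changes
  with `S`.

## Problem sizes

The full study conditions (91 pairs × 30-point grids at dt = 0.05 min) are
desk-scale: one all-pairs sweep of a canonical variant takes about one to
two minutes on a single core with the AE-curve cache enabled; the
reproduction suite in `tests/testthat/test-acceptance.R` runs two full
sweeps plus five focal motif pairs, and the faster structural tests use a
300-min horizon where the study window is irrelevant to the property being
checked.
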