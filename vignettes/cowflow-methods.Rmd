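---
title: "Lumped-parameter circle of Willis hemodynamics and model selection"
author: "cowflow"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Lumped-parameter circle of Willis hemodynamics and model selection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cowflow)
```

## The problem

Computational analyses of anterior communicating artery aneurysms (AComA)
start from an angiographic geometry that is either a *complete* circle of
Willis (all three inflows: left and right internal carotid arteries, ICA,
and the basilar artery, BA — typically from MRA) or a *half* model (a
single ICA inflow tree, typical of DSA, where contrast injected into one
vessel opacifies only that side). The choice matters: the AComA sits on the
bridge between the left and right anterior cerebral arteries, at the
junction of the A1 (pre-communicating) and A2 (post-communicating)
segments, and its inflow can be fed from one side or from both.

`cowflow` implements a desk-scale surrogate for this analysis:

1. a **resistive network model** of the CoW, built on the Hagen–Poiseuille
   law per vessel segment,
2. a **quasi-steady pulsatile solver** for nodal pressures and segment
   flows under prescribed inlet waveforms,
3. cycle-level **wall shear stress statistics** (TAWSS, systolic/diastolic
   WSS, OSI, RRT) and complete-versus-half comparison,
4. the **two-step resistance-ratio rule** for choosing the appropriate
   model from the four A1/A2 resistances, and
5. a seeded **synthetic generator** of patient-like CoW networks so the
   whole pipeline is testable without patient imaging.

## The model and its assumptions

Each vessel segment is a Poiseuille conduit: for a cylinder of radius $r$
and length $L$ carrying fluid of viscosity $\mu$,

$$Q = \frac{\pi r^4 \,\Delta P}{8 \mu L}, \qquad
  R = \frac{8 \mu L}{\pi r^4},$$

so the network is a linear resistor graph. For tapered vessels the package
integrates the series limit exactly under linear radius interpolation,
$R = \tfrac{8\mu}{\pi}\int \mathrm{d}s / r(s)^4$, using the algebraically
regular per-piece form
$\Delta s\,(r_1^2 + r_1 r_2 + r_2^2)/(3 r_1^3 r_2^3)$ (no special-casing of
$r_1 = r_2$). Vascular resistances reported by external tools can be
attached verbatim as `resistance_override`; because every decision the
package makes with resistances is a *ratio*, an unknown common scale is
harmless (a tested invariance).

Kirchhoff conservation at every node plus the flow law per segment yields a
weighted graph Laplacian in the conductances $1/R$. Outlets carry zero
gauge pressure (the conventional cerebral CFD outlet condition; in this
flow-driven model the flow distribution is set by resistances, not by
outlet pressure levels) and are eliminated, leaving a symmetric
positive-definite system solved by dense LAPACK factorization — the systems
are of order ten, so sparse or iterative machinery would be overhead with
no payoff.

**Quasi-steady pulsatility.** The network carries no compliance or
inertance, so each time step is an independent steady solve at the
instantaneous inlet flows; the factorization is done once and reused for
all right-hand sides. This is deliberate: the mechanism under study is
resistance-ratio-driven flow distribution, and adding RC/RL elements would
introduce per-vessel parameters that neither the selection rule nor the
data provide. Consequences worth knowing: flow and pressure respond to the
inlet waveform with zero phase lag, and no segment can reverse during a
cycle unless its driving pressure difference reverses.

**Blood** is Newtonian and incompressible (density 1050 kg/m³, dynamic
viscosity 4 mPa·s) — the standard surrogate at cerebral shear rates, where
shear-thinning has largely saturated. Reynolds numbers realized by the
default configuration sit in the physiologic few-hundred range;
`reynolds_number()` warns above 2000, where a laminar resistive model stops
being meaningful.

**The aneurysm node.** The sac and the ACom junction are collapsed onto a
single `aneurysm` node where both A1 segments deliver and both A2 segments
drain. A purely resistive network cannot represent intrasaccular
recirculation, and a mid-ACom node of degree two cannot express
bidirectional feeding at all (conservation forces through-flow), so the
junction collapse is the only representation in this model class that
supports both one-sided sweep and two-sided collision. Networks that model
a distinct ACom segment are still valid inputs (role `ACom`).

## Wall shear stress statistics

Per segment, the fully developed laminar wall shear stress is
$\tau_w = 4\mu |Q| / (\pi r^3)$, evaluated at the *minimum* profile radius
for tapered segments (the narrowest station carries the highest WSS; a
deterministic worst-case convention). Over the reported cycle:

* $\mathrm{TAWSS} = \tfrac1T \int_0^T |\tau_w|\,\mathrm{d}t$ (trapezoidal);
* systolic/diastolic WSS are the samples at the instants of peak/minimum
  *total inlet inflow* by default — the natural markers in a flow-driven
  model, and configurable as explicit indices because cardiac phases are
  sometimes defined externally (e.g. ECG gating);
* $\mathrm{OSI} = \tfrac12\bigl(1 - |\int \tau_w\,\mathrm{d}t| /
  \int |\tau_w|\,\mathrm{d}t\bigr) \in [0, 0.5]$ and
  $\mathrm{RRT} = 1/((1 - 2\,\mathrm{OSI})\,\mathrm{TAWSS})$, the standard
  literature definitions, adopted here explicitly because the source
  analyses mention these quantities without printing formulas.

Complete-versus-half agreement is quantified by
`compare_models()`: $100\,|\bar{m}_\text{complete} - \bar{m}_\text{half}| /
\bar{m}_\text{complete}$ for the aggregate statistic (TAWSS by default)
over a configurable element set. The default set is the two A2 segments —
the vessels adjacent to the aneurysm that exist in the complete model and
in both half models; which sac surface region to average is a 3D notion
with no 0D analogue, so the element set is left explicit.

## The two-step selection rule

Given the four resistances (left/right A1, left/right A2) on any common
scale:

1. if the larger A2 resistance exceeds the smaller by **more than twofold**
   (`threshold = 2`), ACom flow is effectively one-way and a **half model**
   suffices; otherwise the **complete model** is required;
2. if a half model is indicated, take the side whose **A1 resistance is
   lower** — the dominant feeding artery.

Tie-breaks and edge cases: a ratio of exactly 2 resolves to the complete
model (the rule's wording is "more than"; complete is also the conservative
choice); equal A1 resistances with a half-model indication raise an error
demanding an explicit user choice rather than guessing a side; an A1 ratio
above tenfold triggers a hypoplasia warning, because extreme A1 asymmetry
can dominate the hemodynamics regardless of the A2 comparison and such
anatomies deserve case-by-case review. The decision is invariant under
rescaling all four resistances (tested property), and swapping the left and
right labels mirrors it exactly.

`dominance_from_flow()` is the solver-side counterpart: a side is dominant
when it delivers at least a fraction `dominance_threshold` (default 0.9) of
the cycle-integrated inflow into the aneurysm node. See *Known
limitations* for how far this agrees with the rule in practice.

## Half-model surgery

`split_half(net, side)` reproduces what single-vessel angiography sees: it
keeps the ipsilateral ICA and A1, the aneurysm node and **both** A2
branches distal to it, removes the contralateral A1 and ICA, and by default
removes the posterior circulation (the segments listed under
`roles$posterior`). Posterior handling is a flag (`keep_posterior`) rather
than a hard rule because imaging protocols differ in how much of the
posterior tree a carotid injection shows. The function is pure — the input
network is never modified — and the result re-passes full validation.

## The synthetic generator

`generate_cow()` emulates the *statistical structure* of the study
anatomies, not any particular patient:

* fixed topology: three inlets (ICAs, BA), carotid termini with an MCA
  outflow each, the aneurysm node joining both A1s and both A2s, and a
  posterior tree (BA, two PCAs) tied in through the PComs;
* per-variant A1/A2 resistance ratio ranges, realized *exactly* by setting
  the higher-resistance side's radius to $r\,\cdot\,\text{ratio}^{-1/4}$:
  `one_sided_dominant` (A1 ratio 2.8–4.5, A2 ratio 2.2–3.2, low A2
  contralateral — the pattern of the dominant-side cases),
  `balanced_a2` (A2 ratio 1.05–1.45 with A1 ratio 4.0–6.5 — the
  balanced-A2, strongly A1-asymmetric pattern), `hypoplastic_a1` (A1 ratio
  12–18, low A2 ipsilateral — the reversed-A2 anomaly), and `symmetric`;
* log-normal multiplicative noise (default 5% relative s.d.) on the radii
  of the non-discriminating segments only, so the variant-defining ratio
  guarantees hold for every seed; the symmetric variant mirrors its noise
  between sides so that exact symmetry — and a 50/50 aneurysm inflow
  split — holds for *every* seed, not just in expectation;
* inlet waveforms `mean * (1 + amplitude * pulse(t))` with a von-Mises
  pulse, zero-mean on the sample grid (so the cycle integral is exactly
  `mean * period`) and unit peak at the systolic peak time; defaults:
  ICA mean 4.0×10⁻⁶ m³/s, BA mean 2.0×10⁻⁶ m³/s (the BA carries less flow
  than either ICA), amplitude 0.5, peak at 0.15 of the cycle.

Baseline dimensions: A1 14 mm × r 1.1 mm, A2 22 mm × r 1.1 mm, ICA
20 mm × r 2.0 mm, MCA 30 mm × r 1.4 mm, PCom 15 mm × r 0.7 mm, PCA
30 mm × r 1.0 mm, BA 25 mm × r 1.5 mm — literature-typical adult values,
all overridable. With these, the ACA takes roughly a quarter of each ICA's
inflow and the MCA most of the rest, which matches the usual territorial
split.

Two printed-value fixtures (`generate_case_fixtures()`, cases 4 and 5)
carry published A1/A2 resistance quartets verbatim as overrides
(0.113/0.302/0.203/0.079 and 0.089/0.472/0.285/0.211). Those values come on
a reported scale that is not reconcilable with the Poiseuille formula at
millimetric dimensions (the lengths and radii behind them are not
published); they are accepted as given, and the surrounding segments are
assigned overrides equal to their geometric resistances rescaled by one
common factor so the whole network lives on a single consistent scale.
Since flows under prescribed inflows are invariant to a global resistance
rescaling (tested), the flow pattern is unaffected by that factor.

**What the generator does not emulate:** real vessel tortuosity and taper,
sac geometry, inter-patient waveform variability, collateral anatomy
beyond the fixed topology, and any 3D flow feature. Tests passing on
synthetic networks therefore validate the network mathematics and the
selection logic — not patient-specific hemodynamic accuracy.

## Numerical choices

* Time discretization: step 0.02 s, cycle 1 s, three cycles with the last
  reported — the conventional cerebral-CFD configuration; because the model
  is stateless the earlier cycles are exact copies, and they are retained
  only so the configuration mirrors the transient convention. Reported
  cycles include both endpoints so trapezoidal cycle integrals close.
* Waveform evaluation: periodic linear interpolation.
* Tapered resistance: exact piecewise closed form (above); profile ranges
  not covering the full segment length are extended at the nearest sampled
  radius.
* Conservation is monitored (`conservation_residual()`), not enforced by a
  tolerance: direct factorization keeps it at rounding level (~1e-16
  relative in the shipped cases; the test bound is 1e-9).
* Degenerate inputs fail loudly: non-positive radii or resistances,
  disconnected graphs, missing outlet, zero total aneurysm inflow
  (undefined fractions), identically zero WSS series (undefined OSI), OSI
  of 0.5 or zero TAWSS (undefined RRT) are all errors, not NaNs.

## Problem sizes

The shipped test suite and the reproduction script run pulsatile solves of
13-segment networks (51 time steps each) over populations of 50 seeded
realizations per variant, plus a handful of hand-reducible oracle networks
(≤ 6 segments). These sizes were chosen because the quantities of interest
— ratios, fractions, agreement rates — are fully converged at them: the
solver is direct and deterministic, and population rates stabilize well
below 50 realizations.

## Known limitations

* **The aneurysm inflow fraction is an A1-ratio statistic.** Under equal
  prescribed ICA inflows, the fraction of aneurysm-node inflow delivered by
  one A1 is (empirically, across the geometry ranges shipped) a
  near-monotone function of the A1 resistance ratio and is almost
  insensitive to the A2 ratio: prescribed inflows act as current sources,
  so the contralateral carotid junction stays pressurized and keeps
  feeding. The fraction reaches the 0.9 dominance threshold only at
  hypoplastic-grade A1 asymmetry (order tenfold); with a threefold A1
  difference it plateaus near 0.6–0.75. In particular, a balanced-A2
  anatomy with a fivefold A1 asymmetry yields a *larger* one-sided fraction
  (0.72 on the shipped case-5 fixture) than a dominant-pattern anatomy with
  a threefold A1 asymmetry (0.63 on the case-4 fixture). The one-sided
  sweep versus two-sided collision distinction reported from 3D
  streamlines is a sac-level geometric effect that a 0D junction flow
  budget cannot reproduce, at any threshold. `dominance_from_flow()` is
  therefore reliable for detecting hypoplasia-grade one-sidedness and for
  ruling dominance *out*, but it does not reproduce streamline-level
  dominance classifications for moderate A1 asymmetry; the resistance-ratio
  rule (`select_model()`) is the intended primary instrument, and
  `selection_report()` flags disagreement between the two rather than
  hiding it.
* For the same reason, complete-versus-half TAWSS differences in the 0D
  model track A1 asymmetry: they reproduce the left-half-closer-than-right
  ordering for left-dominant anatomy, but not the published magnitude
  contrast between the dominant-pattern and balanced-A2 patient cases.
* No compliance, inertance, autoregulation, or distal bed models: outlet
  segments act as the entire downstream impedance.
* WSS is the Poiseuille closed form on the minimum radius — a scale
  surrogate for comparisons, not a pointwise wall map.
* The selection rule's twofold threshold is used as published; the package
  does not attempt to re-derive or recalibrate it.
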