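# cowflow

Lumped-parameter (0D) circle of Willis hemodynamics and angiographic model
selection for anterior communicating artery aneurysms (AComA).

## What it does, and for whom

CFD analyses of AComA hemodynamics start from either a *complete* circle of
Willis (CoW) geometry — all three inflows (left/right internal carotid
arteries and the basilar artery), typical of MRA — or a *half* model — a
single-ICA inflow tree, typical of DSA. Which one is appropriate for a
given patient depends on whether the aneurysm, sitting at the junction of
the left and right A1 and A2 segments, is fed from one side or from both.

`cowflow` is aimed at researchers in cerebrovascular biomechanics who want
a fast, fully testable desk-scale surrogate for that question. It models
the CoW as a resistor network via the Hagen–Poiseuille law

    Q = π r⁴ ΔP / (8 μ L),        R = 8 μ L / (π r⁴)

solves nodal pressures and segment flows at each time step of a prescribed
pulsatile inlet cycle (Kirchhoff conservation, zero-gauge outlet
pressures), computes cycle-level wall shear stress statistics (TAWSS,
systolic/diastolic WSS, OSI, RRT), performs complete→half model surgery,
and implements the two-step resistance-ratio rule:

1. if one A2 segment's resistance is **more than twice** the other's, use a
   **half model**; otherwise use the **complete model**;
2. if a half model is indicated, choose the side with the **lower A1
   resistance** (the dominant feeding artery).

A seeded synthetic generator produces patient-like CoW networks (one-sided
dominant, balanced-A2, hypoplastic-A1, symmetric variants) and inlet
waveforms, so the whole pipeline runs without patient imaging. See the
methods vignette (`vignettes/cowflow-methods.Rmd`) for the model,
assumptions, defaults, and known limitations.

## Worked example

Case 4 of the packaged fixtures carries the published resistance quartet
(left/right A1 = 0.113/0.302, left/right A2 = 0.203/0.079 Pa·s/m³):

```r
library(cowflow)

fx  <- generate_case_fixtures()
net <- build_network(fx$case4)

select_model(quartet_from_network(net))
#> <selection_decision> model = left_half
#>   A2 ratio = 2.57 (threshold 2), A1 ratio = 2.67, dominant side = left
#>   A2 resistance ratio 2.57 exceeds 2: one-sided ACom flow; left A1 has the lower resistance and dominates

selection_report(net, default_inlet_waveforms())
#> <selection_report>
#>   rule decision: left_half (A2 ratio 2.57)
#>   flow dominance: none (f_left = 0.634, f_right = 0.366)
#>   TAWSS rel. diff: complete vs left half 32.8%, vs right half 57.1%
#>   NOTE: rule-based and flow-based conclusions disagree
```

Reading the numbers: the A2 resistances differ by 2.57× (> 2), so the rule
selects a half model, on the left because the left A1 resistance is 2.67×
lower — the left ICA is the dominant feeder. The pulsatile solve agrees
directionally (the left A1 delivers 63% of the aneurysm-node inflow, and
the ACom crossing runs from the left side into the right A2 throughout the
cycle), and the complete model's A2-segment TAWSS is much closer to the
left-half model's than to the right-half model's (32.8% vs 57.1%). The
report flags that the flow-based *dominance* call ("none") is weaker than
the rule's: under equal prescribed ICA inflows the 0D inflow fraction
reaches the 0.9 dominance threshold only for near-hypoplastic A1 asymmetry
— a documented limitation of 0D flow budgets (see the vignette's *Known
limitations*), which is why the resistance-ratio rule is the primary
instrument and the flow check is reported alongside rather than merged.

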