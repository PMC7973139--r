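---
title: "Models and methods behind enactraff"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind enactraff}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(enactraff)
```

# Scope

`enactraff` quantifies how a membrane regulator changes epithelial sodium
channel (ENaC) activity in the *Xenopus* oocyte expression system, where
whole-cell current is the product N · P_o · i (surface channel number,
open probability, unitary current). The package implements the complete
measurement chain — annotated-trace metrics, I/V and permeability
analysis, the MTSET retrieval calculus with its forward kinetic model, and
single-channel amplitude-histogram analysis — together with seeded
synthetic-data generators so that every estimator can be validated against
known ground truth.

# Physical constants

All Nernst-type calculations use the thermal voltage RT/F collapsed into a
single number, default **25.5 mV**. The recordings were made at "room
temperature" rather than a controlled temperature; 25.5 mV (≈ 23 °C) is the unique
choice that reproduces both reference equilibrium potentials of the
recording conditions (E_Cl = −77.4 mV from 104/5 mM, E_K = −79.4 mV from
4/90 mM) to 0.1 mV, and it is configurable. The liquid-junction potential at the
pipette/NaCl-bath interface is **12 mV, bath positive**, so a −70 mV
nominal holding potential corresponds to an effective trans-patch
potential of −82 mV. Chloride totals of the built-in solution presets are
derived once from the salt recipes and stored (modified ND96: 104 mM);
activity coefficients are deliberately ignored.

# Whole-cell metrics

ΔI_Ami is the plateau difference between amiloride-free and
amiloride-containing bath; ΔI_Ca²⁺Mg²⁺-Removal is the difference between
the most-inward current during divalent-free superfusion and the
preceding baseline plateau. Plateaus are averaged over the **final 20 %**
of each annotated segment — steady levels are conventionally judged by
eye; the tail window is our concrete, reproducible rule, configurable through
`metric_windows()`. Two further conventions:

* Traces store signed currents (inward negative); ΔI metrics are reported
  as non-negative magnitudes. A washout plateau *less* inward than the
  amiloride baseline is clipped to 0 and flagged rather than propagated
  as a negative current.
* The brief Ca²⁺-activated chloride transient that can precede divalent
  re-addition is excluded from the divalent-removal extremum by a 5-s
  guard window at the segment end (duration our choice).

The relative inhibition statistic is computed from batch-normalized
currents. The raw form of the statistic, (ΔI/ΔI_mean,control − 1)·100 %,
is negative for inhibition, while summary figures conventionally report
positive percentages; the package returns **positive-for-inhibition** and
documents the sign flip. Batch
normalization divides each oocyte by the mean of the control group *from
its own donor batch*; it errors, naming the batch, if any batch lacks
controls. Group summaries report mean, SEM (sd/√n, `NA` for n = 1), the
oocyte count n and the batch count N.

# I/V analysis and permeability

I/V curves average the final 100 ms of each 2-s step of the standard
nine-step protocol (−120 mV start, +20 mV increments). The reversal
potential is found by **piecewise-linear interpolation** between the
bracketing sign change (the crossing nearest 0 mV when there are
several); interpolation is the simplest defensible estimator here, and a
local three-point linear fit is exposed as an alternative. Endogenous currents
are removed by subtracting the batch-matched control-mean curve
pointwise, treating the control mean as fixed. The permeability ratio
uses the simple exponential P_X/P_Na = e^(ΔE_rev/(RT/F)); the residual
1 mM Na⁺ of the NMDG bath is ignored, matching that form.

# The trafficking model and the retrieval calculus

The forward model has two surface pools: covalently modified channels
(open probability `po_modified`, default exactly 1 — empirically the
modification drives P_o close to 1; the exact-1 default makes the
calculus an exact inverse and is configurable for sensitivity analysis) and unmodified channels
(`po_baseline`). Between modification events

* dN_mod/dt = −λ·N_mod,
* dN_unmod/dt = J − λ·N_unmod,

solved in closed form (no integration error). A modification event
instantaneously converts all unmodified channels; the 5-min reagent
exposure is treated as complete because it was verified to reach a
plateau. `steady_state()` sets J = λ·N₀ so the total surface count is
conserved — the regime indicated when a second MTSET application
restores the current to its initial post-MTSET level. First-order
retrieval is an assumption: through-origin linearity of the cohort
regressions of retrieval on expression (an unsaturated endocytic
machinery) justifies it empirically but does not exclude other kinetics.

The inverse calculus estimates, per oocyte,

* P_o(initial) = ΔI_Ami(before)/ΔI_Ami(0), clipped to [0, 1] with a flag
  on noisy series rather than failing;
* ΔI_Insertion = ΔI_2ndMTSET·P_o/(1 − P_o);
* ΔI_Retrieval = ΔI_Ami(0) − (ΔI_Ami(70) − ΔI_Insertion).

Under the exact steady-state model the corrected remaining fraction
1 − ΔI_Retrieval/ΔI_Ami(0) equals the modified-pool survival e^(−70λ),
and the summary-ratio identity f = (raw − P_o)/(1 − P_o) — a closed
form derived in-package — gives the same number from the two headline
ratios alone (0.62, 0.3 → 0.457 ≈ 46 %). Cohort regressions of
ΔI_Retrieval on ΔI_Ami(0 min) are **fit through the origin**
("proportionality coefficients"); a free-intercept fit is available as a
diagnostic. The through-origin slope k weights large oocytes more than
the mean of per-oocyte ratios, which is why the two statistics can
legitimately differ on the same cohort.

# Single-channel analysis

The closed level is the amiloride-segment mean. Traces are digitally
refiltered to 250 Hz before histogramming; the filter is a Gaussian FIR
kernel with σ_t = 0.1325/f_c (the standard patch-clamp Gaussian-filter
relation) — implemented in-package because no DSP dependency is
available, and skippable (`refilter_hz = NULL`) for exactness checks.
Histograms use a default **0.02 pA** bin width (a conventional choice)
with the closed level at a bin center. Modes are kernel-smoothed local
maxima refined by per-mode Gaussian fits with a weighted-mean fallback
(a mixture-model package would add a dependency for no accuracy gain at
these separations); modes below 0.1 % dwell mass are discarded — that
threshold is our automated proxy for "visual inspection" when counting
the apparent channel number N. Levels are assumed contiguous from the
closed level, adequate for the N ≤ 3 patches the P_o(app) rule targets.
NP_o is Σ k·(mass at level k); P_o(app) = NP_o/N is reported only for
N ≤ 3, `NA` otherwise. The chord conductance uses the LJ-corrected
potential (−82 mV) by default; at 0.38 pA both −82 and −70 mV round to
5 pS, so the choice is documented rather than consequential.

# Synthetic data: the stated world

The generators emulate the *statistical structure* of the recordings;
per-oocyte raw data are not available, so distributions are calibrated
to reported means ± SEM and the following choices, made once:

* per-oocyte expression: lognormal, CV **0.5** (wide scatter of
  individual points; no distribution is stated);
* batch effects: multiplicative lognormal factor, CV **0.2** — invented,
  needed for batch normalization to be meaningful;
* solution-exchange kinetics: 2-s exponential relaxations — cosmetic,
  since metrics read plateau tails;
* gating: independent identical two-state channels (amplitudes and NP_o
  are constrained by measurement; dwell kinetics are not), mean open
  dwell 150 ms at
  P_o = 0.3, Gaussian noise 0.05 pA;
* whole-cell noise 5 nA; MTSET-series noise 2 % of scale in the recovery
  properties.

What a green test establishes: estimator correctness on data generated by
the model the estimator assumes, at realistic noise. What it does not:
robustness to capacitive/series-resistance artifacts, drift, baseline
wander, correlated noise, recycling pools or Na⁺-feedback — all outside
the generator's world. Cohort-level quantities that depend on
per-oocyte raw data (regression slopes, mean inhibition, absolute
reversal potentials) are covered by parameter-recovery properties, not
equality targets.

# Numerical choices and degenerate inputs

* Trafficking dynamics use closed forms; conservation holds to machine
  precision and is tested at that tolerance.
* Reversal estimation is exact on linear I/V data; on curved data its
  error is bounded by the grid and checked against a dense-grid oracle.
* λ = 0 is handled as a static membrane (flux 0), not an error;
  P_o(initial) = 1 makes the insertion correction undefined and errors.
* `raw_remaining < P_o(initial)` is rejected as inconsistent with the
  steady-state model rather than silently producing a negative fraction.
* Determinism: every generator takes an explicit integer seed; the
  pipeline writes the seed and a config hash into its provenance record,
  and reruns are byte-identical.

# Known limitations

Mean-field deterministic trafficking (no stochastic channel counts);
two-state gating only; no automatic segment detection from unannotated
traces; no GHK current-equation fitting (only the reversal-shift ratio);
hypothesis testing beyond mean ± SEM is delegated to standard R routines
and is not re-implemented here.
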