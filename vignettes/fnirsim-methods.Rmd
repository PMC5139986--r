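---
title: "Model and methods behind fnirsim"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Model and methods behind fnirsim}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fnirsim)
```

# The problem

Haemodynamics-based neuroimaging infers neuronal activation from regional
blood-flow changes. In fNIRS the optical path crosses the scalp and skull, so
the measured oxy- and deoxyhaemoglobin changes (ΔHbO2, ΔHHb) mix a cerebral
component with an extracerebral one, and both are driven by systemic
physiology — arterial pressure, CO2, arterial saturation — that can change
during a task. `fnirsim` is a forward simulator of these contributions. It is
built to answer two questions: *which combinations of systemic changes can
mimic or mask the canonical activation signature* (a rise in HbO2 with a fall
in HHb), and *how much of a given measurement is attributable to the scalp
versus the brain*.

# The cerebral compartment

The cerebral model couples a regulated vascular bed to a reduced model of the
terminal mitochondrial electron transport chain.

## Blood flow and regulation

Flow is driven by mean arterial pressure across an arterial conductance that
scales with a characteristic vessel radius by Poiseuille's law, `G ∝ r^4`,
with arterial blood volume scaling as the vessel cross-section, `Va ∝ r^2`.
The radius relaxes with a 10 s time constant towards a set-point chosen so
that the delivered flow tracks a demanded flow

```
F_dem = 1 + g_CO2f·ΔPaCO2/PaCO2_n + g_uf·(u − 1)
          − g_O2f·ΔO2_sensed/O2_n − g_saf·ΔSaO2/SaO2_n
```

multiplied by a residual passive pressure dependence `1 + a_P·ΔPa/Pa_n`.
The residual slope `a_P` represents incomplete autoregulation: with the
default `a_P = 0.2`, flow changes by only ±5 % across the 75–125 mmHg
pressure range where a passive bed would change by ±25 %. The tissue-O2
feedback acts through a slow (60 s) sensed-O2 state, which produces the
delayed partial re-constriction seen after CO2 or demand steps once tissue
oxygenation has risen.

Cerebral venous volume is held constant (the venous bed is confined by the
skull and is not the locus of the fast arterial reactivity being modelled);
venous saturation follows from an instantaneous balance between blood-side
O2 extraction and diffusion into tissue, which is linear in SvO2 and solved
in closed form at every step.

## The metabolic chain

Three electron-transfer reactions — substrate → CuA, CuA → a3, a3 → O2 —
carry rates `f1, f2, f3` that are linear in the proton motive force Δp and
in the natural logarithms of the donor/acceptor pool concentrations, e.g.

```
f1 = lam_f1 + lam_f1_p·Δp + lam_f1_a·log[CuA_ox]
```

(and analogously for `f2` with `log[CuA_red]`, `log[a3_ox]`, and `f3` with
`log[a3_red]`, `log[O2]`). One naming caveat is documented in
`?metabolic_rates`: the coefficient of the `log[a3_ox]` term belongs to the
second rate equation and is named `lam_f2_b` here, although it is sometimes
printed with an f1 subscript. A substrate-supply dependence is deliberately
omitted on the assumption that supply is not limiting in functional
experiments with healthy subjects.

Demand `u` acts on metabolism through the proton motive force: Δp is pumped
in proportion to the three rates and consumed in proportion to `u·Δp`. A
demand increase therefore lowers Δp, disinhibits all three reactions and
raises oxygen consumption (CMRO2 ∝ f3). Oxidised/reduced pool pairs are
integrated with exactly opposite derivatives, so CuA and a3 totals are
conserved to solver precision.

The slope coefficients are parameterised as elasticities (fractional rate
change per unit log-concentration, or per fractional Δp change) with signs
fixed by the thermodynamics: Δp opposes every forward rate; each rate
increases with its donor and acceptor availability; `lam_f3_O ≥ 0` so the
chain shuts down as O2 → 0. The NIRS-visible CCO redox output is the change
in oxidised CuA, the simplest marker consistent with the model structure.

## Calibration

The model's intercepts and transport constants are solved analytically so
that the configured baseline (Pa 100 mmHg, PaCO2 40 mmHg, SaO2 96 %, u = 1,
tissue O2 0.024 mM, Δp 145 mV, SvO2 70 % — the venous saturation baseline is
an assumption, exposed in the configuration) is an *exact* fixed point. That
makes `calibrate_cerebral()` deterministic: no fitting noise, no seed
dependence, and the baseline-flatness and fixed-point tests hold to machine
precision rather than to a fitted tolerance.

The regulation gains are genuinely free parameters: no numeric values are
available for the linearised regulation they stand in for. They were chosen
once, by steady-state analysis against the qualitative physiology the model
must reproduce, and are fixed as package defaults:

* `g_CO2f = 2.0` — ≈5 %/mmHg flow reactivity to CO2, inside the accepted
  3–6 %/mmHg physiological range;
* `g_uf = 0.8` — activation (u = 1.25) raises flow ≈20 % while CMRO2 rises
  ≈10 %, the classic ~2:1 flow–metabolism uncoupling that produces venous
  hyperoxygenation and hence the HHb fall of the activation signature;
* `a_P = 0.2`, `g_O2f = 0.15` — strong but incomplete autoregulation with a
  mild, slow tissue-O2 feedback. These two jointly control the
  false-negative geometry: the residual passive slope makes flow lag demand
  at reduced pressure (suppressing the HHb undershoot) and overshoot at
  raised pressure (suppressing the HbO2 rise via radius constriction), which
  is what allows single-factor false negatives to exist at all.

`calibrate_cerebral()` re-verifies the directional targets (pressure up ⇒
both species fall; CO2, O2 or demand up ⇒ HbO2 up, HHb down; CMRO2 monotone
in demand) on every build and fails loudly, listing violated constraints, if
a user configuration breaks them.

## Steady states

`cerebral_steady_state()` does not integrate to equilibrium. At a steady
state the pool derivatives force `f1 = f2 = f3`, and the proton balance then
fixes the common rate as `f = f_n·u·Δp/Δp_n`; given Δp, each rate equation
yields one pool concentration in closed form, ending with the tissue O2 the
chain demands. The only remaining unknown is Δp itself, found by a 1-D root
search on the tissue O2 mass balance. This makes a steady state cost
microseconds, which is what keeps the 21×21 response-surface sweeps and the
population-based scenario searches fast. The returned state is verified
against the full derivative field (relative residual < 1e-8).

# The scalp compartment

The scalp is a Windkessel in parallel with the brain and conditionally
independent of it: no scalp variable depends on any cerebral variable or
vice versa (shared haemoglobin scaling and the venous-saturation constant
are parameters, not state). Flow is estimated either from pressure
(`Fx = lam_Fx + lam_Fx_p·Pa`, coefficients fitted by least squares to a
packaged *synthetic* pressure–flux table, since the original recordings are
not redistributable) or from measured laser-Doppler flux
(`Fy = Flux_y·Fy_n`, with `Fy_n` defaulting to the pressure-model baseline
so the two variants agree at rest). Conductance follows `G = F/Pa`, radius
and arterial volume follow the same Poiseuille/cross-section scalings as the
cerebral bed, and the venous pressure obeys

```
dPv/dt = (G·(Pa − Pv) − Pv·Gv) / Cv
```

— the compliance divides the whole balance (dimensional analysis leaves no
alternative reading). Baseline normalisation fixes total volume at 1 with a
3:1 venous:arterial split, a venous resistance share `Rfrac_v = 0.1` (so
`Pv = 10 mmHg ≪ Pa`, and `Pv*/Pa = G/(G+Gv)` exactly), and a compliant
share `Volc_frac = 0.1` of the venous volume. The dynamic compliance `Cv`
(default 2.0 normalised-flow/mmHg, giving a venous time constant
`Cv/(G+Gv) = 20 s`) is expressed in flow units, while the volume excursion
is mapped through the `Volc_frac` split
(`Vv = Vv_nc + Volc_frac·Vv_n·Pv/Pv_n`); the two are the same physical
compliance written in the model's two normalised unit systems. A single `Gv`
serves both the compliant discharge and the through-flow path — the split
between those roles is not separately identifiable at this level of detail.

Scalp arterial blood carries the systemic saturation unchanged; venous blood
sits at the cerebral baseline venous saturation, and no scalp metabolism is
modelled. Two consequences are worth remembering when interpreting output:
without a saturation change the scalp ΔHbO2 and ΔHHb always co-vary (it
cannot produce opposing changes), and because venous saturation is high the
scalp ΔHHb is systematically smaller than ΔHbO2 — the scalp's impact on the
measured HbO2 may therefore be overestimated relative to HHb.

# Observation model

Haemoglobin outputs are volume-weighted saturations scaled by a shared
haematocrit/vessel-density factor (`hb_scale`, default 100 µM per unit
normalised volume — chosen so a demand step produces a few µM, the scale of
real fNIRS responses; absolute values are relative unless the user supplies
their own scaling). Changes are taken against the first sample, so every
series starts at exactly zero. The merged output is a non-negative weighted
sum of the compartments, pure post-processing that never feeds back into the
dynamics.

# Simulation and signal conditioning

`run_simulation()` integrates the joint system (cerebral state, both scalp
variants) with `deSolve::lsoda` at absolute/relative tolerances 1e-8/1e-6,
`hmax = 1 s` so step protocols are never skipped, and output sampling
(default 1 Hz) decoupled from the solver's internal steps. The protocol
builders cover the two study designs: single- or multi-input square steps
between the baseline and range bounds, and a multi-frequency protocol in
which every input oscillates at a distinct harmonic of the segment length,
making the input deviations exactly orthogonal over the segment so the
compartment responses are linearly independent and separable.

Conditioning mirrors standard practice: laser-Doppler flux is normalised by
the *median* of an initial 2-min window (robust to transients in the
window); smoothing is a 60 s sliding mean, **centered**, with
symmetrically-shrinking windows at the edges — the centering and the edge
rule are choices this package fixes and documents, made to avoid trimming
the short 2-min baselines; resampling is linear interpolation with endpoint
preservation.

# Scenario search

The activation template is the model's own steady response to `u = 1.25`
with everything else at baseline; the three non-activation templates are no
change (FN1), the HbO2 rise with flat HHb (FN2), and the HbO2 rise with an
HHb rise (FN3). Classification minimises the total absolute error against
the templates, with ties broken by fixed template order. The false-response
search runs a small seeded differential-evolution optimiser over step
amplitudes of the chosen free inputs within their normal ranges — with SaO2
capped at its baseline, since spontaneous saturation *increases* are
implausible in functional experiments — minimising the same total absolute
error, so the optimiser and the classifier share one metric. A scenario
counts as "matched" when its distance falls below 15 % of the activation
magnitude `|ΔHbO2_act| + |ΔHHb_act|`; the threshold is a package constant
fixed at design time. Results are stochastic under the seed and neither
unique nor necessarily optimal; the meaningful quantity is the achieved
objective, not the argument values.

The choice of a *steady-state* objective (ignoring transients) is a real
design decision with a consequence that deserves honesty: with two free
systemic inputs the steady-state map (Pa, PaCO2) → (ΔHbO2, ΔHHb) is a smooth
2-D-to-2-D map, and any template inside its image — not only FN1 — can be
matched exactly. In this calibration the FN2 target is reachable at reduced
pressure with mildly reduced CO2; this is a genuine property of the model
(the same region the surface sweep classifies as FN2 cells), and it is a
stronger statement of the confounding risk than a shape-sensitive
(time-course) objective would make, because regulation transients that a
time-course match would penalise are unlikely to be identifiable in real,
noisy, filtered data anyway.

# Attribution analytics

Cross-correlation (via `stats::ccf`, demeaned, lags up to ±2.5 min) reports
the peak correlation and its lag; the Pearson coefficient is the lag-0
value. Dynamic time warping is implemented directly as the textbook
dynamic programme: symmetric steps (diagonal/vertical/horizontal), absolute
difference local cost, no global window, closed-end alignment (open-end
variants exist but closed-end is used and stated). It reports the warp `W`
(mean absolute difference of the two alignment index vectors, in samples)
and the final distance `D`; the backtrace prefers the diagonal on ties, so
identical inputs give exactly `W = 0, D = 0`. Because DTW is
scale-sensitive, modelled signals are min–max rescaled onto the measured
range first. The two-compartment attribution minimises the Euclidean error
of a non-negative weighted sum over the concatenated HbO2 and HHb channels —
one (S, C) pair shared by both, encoding the assumption that both channels
are contaminated by scalp to the same degree — using box-constrained
L-BFGS-B from the clipped least-squares and single-compartment starts, which
makes the fit deterministic and guarantees the two-compartment residual
never exceeds the best single-compartment fit.

# What the synthetic data does and does not emulate

All test inputs are generated by the package itself: step protocols at the
tabulated range bounds, orthogonal multi-frequency drives, and noisy
mixtures of simulated compartment signals with known weights and additive
Gaussian noise at 10 % of signal range. These emulate the *structure* of
functional recordings — independent systemic drives, superposed compartments,
instrument noise — but not their full statistics: no Mayer waves or other
spontaneous oscillations (inputs not explicitly driven stay constant), no
heart-beat pulsatility (mean pressure is the input), no movement artefacts,
no inter-subject parameter variability, and no photon-transport weighting of
compartments by source–detector separation (separations are labels only).
Passing tests therefore demonstrate internal consistency and the qualitative
confounding mechanisms, not subject-level quantitative prediction.

# Numerical choices and problem sizes

Stiffness from the small redox pools (sub-second turnover) is handled by
`lsoda`'s implicit mode; tolerances 1e-8/1e-6 throughout. Steady states use
the 1-D root reduction described above with a bracketing scan over
0.3–2× the baseline proton motive force and `uniroot` at 1e-12. The test
and acceptance workloads use the study's own sizes where they are stated —
21×21 response surfaces, 2.5 min correlation lags, 60 s smoothing, 1 Hz
sampling, 10 optimiser seeds, 100-replicate noise studies at n = 200 — and
600–1000 s protocols, long enough for the slowest (60 s) feedback channel to
settle by a wide margin.

# Known limitations

* The cerebral compartment is a reduced model: one regulated conductance,
  a constant venous volume, linearised capillary oxygen handling. It
  preserves the mechanisms the analyses rely on (autoregulation, CO2/O2
  reactivity, demand coupling, O2-limited metabolism) but not the full
  biophysical detail of larger models.
* Scalp flow ignores its dominant physiological drivers (sympathetic tone,
  temperature, cardiac output); the pressure-based variant is an admitted
  first-order stand-in, and the packaged fit table is synthetic.
* µM outputs are relative to the configured haemoglobin scaling.
* The scenario-search "matched" threshold and the steady-state objective
  are package conventions; both are configurable.
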