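---
title: "Modelling conduction velocity in segmentally remyelinated axons"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling conduction velocity in segmentally remyelinated axons}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

In myelinated axons the action potential jumps from one node of Ranvier to
the next, and the conduction velocity (CV) is set largely by the nodal
separation ℓ and the electrical properties of the node. When a segment of
myelin is lost and rebuilt, the new sheaths are shorter and thinner: a
remyelinated segment typically carries two internodes of roughly half the
original nodal separation. As remyelination accumulates — with ageing, or
after demyelinating insult — conduction slows.

The question this package addresses is *how much* of that slowing is
explained by the mere count of short internodes, and how much by their
*arrangement*. The central objects are:

* a **benchmark velocity** `v̄(p)`: the speed a partially remyelinated axon
  would have if every internode were traversed at the speed it has in the
  corresponding uniform axon. With a fraction `p` of original internodes
  remyelinated, reciprocal speeds mix linearly,
  `1/v̄(p) = (1-p)/v_long + p/v_short`
  (`benchmark_velocity()`);
* a discrete-cable **simulator** that measures the actual CV of any
  internode arrangement; and
* a **perturbative transition-delay estimator** that attributes the
  difference to the nodes where internode length changes.

The empirical pattern the package reproduces: randomly placed remyelinated
segments conduct *more slowly* than the benchmark, because an action
potential loses more time at a long-to-short transition than it gains at a
short-to-long transition. The asymmetry per transition is small, but a
random arrangement at `p = 0.5` contains about 35 transitions over a
70-internode measurement span, so the losses compound.

## The discrete cable model

Nodes of Ranvier are short (1 μm against internodes of 575–1150 μm), so
each node is treated as a single isopotential compartment with membrane
capacitance `π·d·μ·Cm`. Internodes are wrapped in many lamellae; with
membrane resistance boosted and capacitance attenuated ~100-fold, their
transmembrane current is negligible and the intracellular potential is
linear along them. Each internode then acts as a pure axial resistor, and
the current entering node *n* from its neighbours gives the discrete cable
equation

```
π d μ (Cm dVn/dt + I_ion(Vn)) = (π d²/4 Rc) [ (V(n+1)-Vn)/ℓ(n) + (V(n-1)-Vn)/ℓ(n-1) ]
```

where each gap uses *its own* nodal separation, so unequal flanking
internodes (the transition nodes) are handled by construction. Ends are
sealed; the stimulating electrode sits ten internodes from the proximal
end to keep boundary effects away from the measurement span.

Default fibre parameters (those of a 10 μm motor fibre): node diameter
`d = 3.3 μm`, node length `μ = 1 μm`, cytoplasmic resistivity
`Rc = 70 Ω·cm`, nodal capacitance `Cm = 2 μF/cm²`, nodal separation
`ℓ = 1150 μm` (halved to 575 μm in remyelinated segments), `g`-ratio 0.69.

**Active membrane.** The nodal ionic current uses classical
Hodgkin–Huxley kinetics (`hh_model()`: gNa = 120, gK = 36,
gL = 0.3 mS/cm²; ENa = +50, EK = −77 mV; resting potential −65 mV). The
motor-fibre channel set this geometry originally came with (fast and
persistent sodium, slow potassium) is not published in a form this package
could faithfully reuse, and none of the package's quantitative worked-example
results depend on it — the analytical machinery takes the two uniform
CVs as *inputs*. The membrane interface (state initialisation, gate
stepping, ionic current) is generic, so a different nodal model can be
plugged in without touching the solver. Two consequences of the HH choice
are worth keeping in mind:

* absolute simulated CVs are those of an HH node (≈ 10–16 m/s here), not
  the ≈ 32–40 m/s of the mammalian motor fibre; all qualitative structure
  (√ℓ scaling, transition asymmetry, benchmark suppression) carries over;
* the leak reversal is re-balanced at construction so the configured
  resting potential is an exact fixed point — an unstimulated fibre holds
  its resting state to machine precision indefinitely.

An optional `leaky_cable` mode inserts a passive RC compartment per
internode whose conductance scales inversely with the lamella count
`f·(1/g − 1)` (default attenuation `f = 100`), for qualitative exploration
of thin (large `g`-ratio) remyelinated sheaths. It carries no quantitative
claims.

## Velocity theory

For a uniform axon in the ideal-internode regime (`μ ≪ ℓ`), the
travelling-wave analysis of the discrete cable predicts CV proportional to
`√ℓ` — halving the internode length should slow conduction by
`√2 ≈ 1.41` (`sqrt_scaling_ratio()`). The simulator reproduces this ratio
to within a few tenths of a percent; the full multi-compartment motor-fibre
geometry deviates by ~10% (ratio 1.27 on the printed CVs), which is one
reason the analytical estimates here take measured uniform speeds as
inputs rather than deriving them.

At a transition node flanked by internodes with uniform-axon speeds `v_a`
(incoming) and `v_b` (outgoing), expanding the node's delay-coupled cable
equation to second order and solving perturbatively for the incoming
transit time gives a fractional delay

```
δτa/τa ≈ (v_a − v_b)/v_b · (1 − (2 μ Rc Cm / d) v_a)⁻¹
```

(`transition_delay_fraction()`). The estimator is only meaningful while
the correction factor stays positive; the function refuses otherwise. For
the printed motor-fibre speeds this gives +0.41 crossing long→short and
−0.29 crossing short→long: slowing on entry to remyelinated tissue
exceeds the speed-up on exit. Applied to a half/half (semi-uniform) axon
over the 80,500 μm span, the perturbed travel times give 35.49 m/s
(long→short) and 35.75 m/s (short→long) against a benchmark of
35.67 m/s (`semi_uniform_estimate()`). A composite estimate for a random
arrangement multiplies measured per-transition delays by transition counts
(`composite_estimate()`); with the restricted-sample statistics (17
long→short and 18 short→long transitions at 10.2 and 6.8 μs) it lands at
34.88 m/s, below the benchmark — note the printed delays are rounded to
0.1 μs, which moves the last digit.

`implied_fraction_for_drop()` inverts the benchmark relation in closed
form (reciprocal speed is linear in `p`); a 10% CV drop requires
`p ≈ 0.42` for the motor-fibre speeds and `p ≈ 0.89` for the small-calibre
thin-myelin endpoint speeds (5.61 → 4.99 m/s, an 11% total decrease).

## The synthetic axon generator

`make_uniform_layout()` builds the base axon (120 internodes, 121 nodes).
`remyelinate()` replaces each original internode independently with
probability `p` by an atomic pair of half-length internodes — total length
is conserved, and the per-slot mask is recorded. Ensembles
(`axon_ensemble()`, 500 draws per `p` by default, as in the study design)
use counter-based child seeds derived from `(master_seed, draw)`:
regeneration is bit-identical and independent of evaluation order, with no
global RNG state.

Electrodes are defined by *physical position* (stimulus at 11,500 μm,
recordings at 34,500 and 115,000 μm) and resolved to node indices per
layout (`resolve_electrodes()`): nodes 11/31/101 on the base axon,
21/61/201 on the fully remyelinated one. Because halving preserves node
positions, every draw measures the same 80,500 μm span containing 70
original internode slots. Positions falling between nodes (possible only
for non-halving length ratios) resolve to the nearest node, ties proximal.

What the generator deliberately does **not** emulate: paranode and
juxtaparanode sub-geometry (the idealised cable has none), spatially
correlated lesions (placement is independent per internode), Wallerian
uniformly-shortened patterns, and the redistribution of sodium channels
during remyelination (nodal membranes are identical everywhere). Passing
tests therefore demonstrate the arrangement effect in the idealised
random-placement setting, not a quantitative prediction for any real
fibre class.

## The study pipeline

`run_study()` sweeps the `p` grid. The stimulus protocol follows the
study design: a 0.1 ms rectangular pulse at twice the propagation
threshold of the *fully remyelinated* model (`find_threshold()`, bisection
to 1% between a doubling-found bracket). Each draw's CV is the recording
separation divided by the difference of first −40 mV crossing times
(linearly interpolated between samples). Per fraction, the table records
the ensemble mean and sd, the benchmark computed from the simulator's own
uniform endpoints, and a *uniform-average control*: a uniform axon whose
internode length is the remyelinated axon's average `ℓ/(1+p)`.

Two structural observations from this simulator:

* the control tracks the benchmark to within ~1.5%. Because CV here
  follows the √ℓ law almost exactly, the control sits slightly *below*
  the benchmark and, at `p = 0.5`, essentially on top of the suppressed
  ensemble mean — the clear separation between control and ensemble seen
  with the motor-fibre membrane is a model-dependent quantity;
* at fixed composition (exactly 35 of the 70 span slots remyelinated,
  `remyelinate_exact()`), CV still decreases with the number of
  transitions, but the per-transition delays measured on isolated
  transitions strongly sub-add at this density (mean suppression
  corresponds to ~3 μs per transition rather than the isolated ~16 μs
  asymmetry), so the count explains only a small share of the
  fixed-composition variance. The fixed-composition draws used to test
  this hold the tract outside the measurement span uniformly normal, so
  that arrangement within the span is the only varying factor.

`restricted_sample()` instead *conditions* binomial draws on their span
count, mirroring the restricted-sample analysis of the study (about 9.5%
of `p = 0.5` draws carry exactly 35 of 70).

## Numerical choices

* **Units.** Internally mV / ms / nA / nF / μS — an exactly consistent
  set (`nF·mV/ms = nA = μS·mV`), so the solver carries no hidden
  conversion factors; geometry converts once at assembly.
* **Integrator.** Fixed step `dt = 5×10⁻⁴ ms`. The linear axial coupling
  (tridiagonal) is advanced by Crank–Nicolson with a Thomas factorisation
  computed once; gates use the Rush–Larsen exponential update (exact for
  frozen voltage, unconditionally in [0,1]); the ionic current is
  evaluated explicitly at the start-of-step voltage. Halving `dt` moves
  the measured CV by well under 1%; on a passive cable the scheme matches
  a dense matrix-exponential solution to better than 0.1%.
* **Detection.** First upward threshold crossing, linearly interpolated
  between the bracketing samples; a trace that never crosses yields an
  explicit no-propagation signal, and ensemble rows flag failures rather
  than dropping them.
* **Windowing.** The default 6 ms window covers the span for CV ≳ 15 m/s;
  drivers extend it once (doubling) before declaring failure. Integration
  stops early once the distal electrode has crossed. |V| > 500 mV aborts
  with a diagnostic.
* **Reporting.** Node indices are 1-based in all user-facing output
  (node 11 means the eleventh node); internal arrays are plain R vectors.

## Problem sizes

The defaults follow the study design (500 draws per fraction, five
fractions). The test suite exercises the same machinery at sizes chosen
for a desk-scale run: reduced ensembles of 8–200 binomial draws for
pipeline behaviour and the suppression test, 1000 fixed-composition draws
for the transition-count correlation (the effect is weak, and the sample
size was chosen by a power calculation on pilot runs), and small 3–40
node fibres for solver validation against dense linear algebra.

## Known limitations

* Absolute CVs and thresholds are those of the HH nodal membrane; only
  the printed uniform speeds reproduce the motor-fibre numbers, as inputs
  to the closed-form estimators.
* The perturbative estimator is first-order and single-transition; at
  high transition density its delays are not additive.
* Myelin is either perfect (default) or a single lumped RC per internode
  (leaky mode); there is no explicit paranode, periaxonal space, or
  tight-junction pathway.
* Ion-channel redistribution during remyelination is not modelled; the
  model corresponds to mature, fully re-equipped nodes.
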