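---
title: "Methods: a driven four-pool model of beta-cell metabolic oscillations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a driven four-pool model of beta-cell metabolic oscillations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(damsim)
```

## The model and its assumptions

`damsim` simulates oscillatory carbon redistribution in glucose-stimulated
pancreatic beta cells. The design premise is deliberate minimalism: rather
than resolving enzyme kinetics, biochemically related intermediates are
lumped into four coarse-grained pools assumed to stay in relative
equilibrium internally — downstream glycolysis (P0: FBP, PEP), the citrate
half of the TCA cycle (P1: Cit, Isocit, αKG), the dicarboxylate half (P2:
Mal, Fum), and the GABA reservoir (P3). The model is **driven, not
autonomous**: normalized Ca²⁺ and ATP waveforms fitted to published islet
recordings are imposed as external inputs, and the pools respond. Nothing
in the package generates oscillations by itself; what it computes is how
prescribed energetic/Ca²⁺ phase structure constrains flux partitioning.

Three assumptions matter most:

1. **Redox–energy identification.** The normalized redox signal is taken
   identical to the ATP waveform, `NADH(t) ≡ ATP(t)`, reflecting tight
   coupling through oxidative phosphorylation. The phase offsets
   `tau_nadh` and `tau_atp` exist precisely to relax this assumption in
   sensitivity studies.
2. **Power-law fluxes.** All five inter-pool fluxes are products of the
   relevant pool level and driver factors (`Ca·P2·P0`, `P1·NADH²`,
   `P3·(1−NADH)`), with no Michaelis–Menten saturation anywhere. The
   quadratic NADH dependence acts as a soft switch confining cataplerotic
   export to the reduced half of the cycle.
3. **Quasi-closed carbon.** The fully oxidative clockwise TCA flux loses
   its carbon as CO₂ and is therefore not represented in the pool
   balances; `J21 = J01` expresses the 1:1 stoichiometry of citrate
   synthase. Consequently dP1+dP2+dP3 = 0 identically and
   P1+P2+P3 = 1.5 with the default initial state (0.4, 0.6, 0.5). This is
   the model's strongest structural invariant and is enforced to 1e-6
   along every trajectory.

Because the right-hand side is linear in the pools for fixed drivers, the
forced system has a unique stable periodic orbit on each conservation
plane; every test that compares "the" orbit relies on this.

## Tunable parameters

All quantities are dimensionless; time is measured in units of the forcing
period T0 = 1.

| parameter | default | meaning |
|---|---|---|
| `k0_ca`, `k1_ca`, `k2_ca` | 22, 15, 10 | branch rates of the pulsatile Ca²⁺ ODE |
| `t1`, `t2` | 0.25, 0.5 | branch switch phases |
| `A0`, `A1` | 0, 0.5 | ATP offset and half-amplitude (span [0, 1]) |
| `tau_atp` | 0 | ATP (and NADH) lead over the Ca²⁺ pulse onset |
| `tau_nadh` | 0 | NADH lead over ATP |
| `k0_p0`, `k0A` | 0.1, 0.2 | algebraic glycolytic level `P0 = k0_p0 + k0A·ATP` |
| `k01` | 7 | PDH inflow constant |
| `k12`, `k13` | 1, 2 | redox-gated cataplerotic constants |
| `k32` | 1 | GABA-shunt constant |

The driver and flux constants are the published values and should be
treated as a calibrated set: they place the periodic orbit where the pool
amplitudes fall in the reported order ΔP1 > ΔP0 > ΔP3 > ΔP2
(0.21/0.20/0.19/0.16 under the default protocol, matching the published
0.22/0.20/0.18/0.16 within the reporting precision of ±0.01).

## Numerical scheme

The Ca²⁺ right-hand side is discontinuous at the branch switch times, so
naive adaptive integration loses order there. `simulate_dam()` integrates
the joint state (Ca, P1, P2, P3) with `deSolve::lsoda` (stiff-capable,
adaptive) **restarted at every branch boundary**, so each solver call sees
a smooth vector field. Branch membership at a boundary is
right-continuous — a measure-zero convention that cannot affect integrals.
Defaults: `rtol = atol = 1e-10`, dense output sampled on a fixed grid of
`dt_out = T0/1000`, 10 periods per run. Halving `dt_out` or tightening
`tol` moves reported amplitudes by less than 1e-4 (asserted in the test
suite). A drift of the conserved total beyond 1e-4 aborts the run.

The Ca²⁺ initial value is not part of the published parameter set; the
package starts at `ca_init = 0` and relies on the large branch rates to
collapse the transient within one period. All reported quantities are
taken from the final period after `n_discard = 5` burn-in periods, and
`periodic_amplitudes()` refuses to report if any pool fails the
periodicity check |x(t_end) − x(t_end − T0)| < 1e-3; with the default
initial pools the orbit is reached well before period 6 (trajectories
started from (0.4, 0.6, 0.5) and (0.5, 0.5, 0.5) agree to < 1e-3 on the
final period).

## Phase annotation convention

Figures in the experimental literature shade an oxidative (Mito_Ox) and a
cataplerotic (Mito_Cat) phase per cycle without giving a formula. The
package defines the boundary operationally by the sign of
dP1/dt = J21 − J12 − J13: net filling of the right-TCA pool is `mito_ox`,
net emptying is `mito_cat`. Under default parameters this yields exactly
two sign changes per period, with the oxidative phase opening just after
the Ca²⁺ pulse onset (at phase ≈ 0.04) — consistent with the narrative
sequence "P2 empties into P1, then P3 refills P2" followed by cataplerotic
backflow. With shifted drivers more than two sign changes can occur; the
annotation then warns rather than fails, and the sweep tables record the
count. A numerically steady trajectory (rates below 1e-8) yields an empty
annotation.

## Sensitivity sweeps

Three studies are packaged as sweep procedures returning tidy tables:
`sweep_k32()` (GABA-shunt strength), `sweep_tau_nadh()` (redox lead/lag)
and `sweep_tau_atp()` (energy–Ca²⁺ phase offset). Default grids are a
package convention chosen to bracket the qualitative regimes, including
limiting cases: k32 ∈ {0, 0.25, 0.5, 1, 2, 4} and τ ∈ {−0.2, −0.1, −0.05,
0, 0.05, 0.1, 0.2}·T0. Each row records final-period amplitudes, extremum
phases, and flags (`bounded`, `periodic`, sign-change count); per-point
failures are flagged rows, not sweep aborts. k32 = 0 is a deliberate
boundary case: the GABA pool then only fills (dP3/dt = J13 ≥ 0), the orbit
is not periodic, and the row reports that honestly. "Preserved phase
relationships" across the k32 grid is operationalized as extremum phases
moving by < 0.05·T0 excluding the k32 = 0 row — a documented convention,
not a published formula.

Two qualitative directions are asserted as regression properties: a modest
positive `tau_nadh` (NADH leading ATP) and a modest positive `tau_atp`
(ATP leading Ca²⁺) both amplify the P1 oscillation relative to the aligned
baseline (0.25 and 0.24 vs 0.21 at τ = 0.05).

## The extended glycolytic pool

The core model slaves P0 to ATP, which makes its waveform sinusoidal;
measured FBP traces are instead sawtooth-shaped. `simulate_dam_extended()`
promotes P0 to a state variable, dP0/dt = J0 − J01, with a regulated
influx

    J0 = s · 1/(1 + α_ATP·ATP²) · 1/(1 + α_Cit·P1²) · P0²/(β² + P0²).

**This functional form is the package's own phenomenological
reconstruction** of the verbal regulatory scheme (ATP and citrate
inhibition of PFK1, FBP self-activation), with P1 standing in for citrate
since citrate belongs to that pool; it is not a published equation, and
its parameters live in the configuration. Defaults (s = 1.2, α_ATP = 4,
α_Cit = 2, β = 0.1, all exponents 2, `p0_init = 0.29`) were hand-tuned
once so that the dynamic P0 oscillates over the same [0.1, 0.3] band the
algebraic model prescribes and so the protocol's ten periods suffice to
reach the orbit. Under these defaults P0 rises through ~65% of the period
and falls through ~35%, with the falling limb steeper than the rising one
— the sawtooth.

A finding worth recording: within this flux family the sawtooth direction
is set by the *timing* of ATP inhibition relative to the Ca²⁺-gated drain
(influx peaks at the ATP minimum, mid-drain, so the minimum of P0 comes
early and the recovery is long), not by the FBP self-activation term.
Removing the positive-feedback factor (β = 0) raises the influx gain — the
Hill factor is ≤ 1 pointwise — and shifts the operating range up, but
leaves the asymmetry direction unchanged; a systematic search over scales,
inhibition strengths, exponents 1–6 and initial conditions found no
surviving periodic regime in which the factor's removal reverses it. The
feedback term's dynamical role here is to sharpen the fall and create a
bistable off-state at low P0 (the reason `p0_init` must not start too low),
not to generate the asymmetry. Tests therefore assert the sawtooth on the
defaults and the gain property of the feedback factor, rather than an
asymmetry reversal.

## Degenerate inputs and edge behaviour

* NADH or ATP arguments outside [0, 1] raise an error rather than clamp:
  the waveform definition guarantees the range, so violations indicate a
  misconfigured driver.
* Zero pools give zero fluxes; every outflow is proportional to its source
  pool, so the non-negative orthant is forward-invariant (asserted from
  extreme partitions such as (0, 1.5, 0)).
* `k01 = 0` removes the only inflow to P1, which then decays monotonically
  and the whole period is annotated `mito_cat`.
* With all rates zero the Ca²⁺ solution is constant, and with `A1 = 0` and
  frozen Ca²⁺ the pools converge to the fixed point of the constant-driver
  flux balance (verified against its closed form in the tests).

## Problem sizes and what the tests do not show

The test suite and the acceptance script run the model at its default
size — 10 forcing periods at 1000 output points per period, a few dozen
such simulations in total — which the package treats as the standard
protocol; every published-value comparison uses exactly this protocol.
Passing tests demonstrate internal consistency (conservation, orbit
independence, solver insensitivity) and agreement with the published
amplitude set under prescribed drivers. They do not validate the model
against raw experimental traces: the drivers are fitted analytic forms,
real FBP/citrate/GABA dynamics contain waveform detail the pooled model
does not represent, and membrane electrophysiology, K_ATP channel gating
and insulin exocytosis are outside the model boundary altogether.

```{r example, eval = FALSE}
traj <- simulate_dam()
periodic_amplitudes(traj)
autoplot(traj, last_period = TRUE)
```
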