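---
title: "An allosteric VSD–pore coupling model of KCNQ1/IKs gating"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{An allosteric VSD–pore coupling model of KCNQ1/IKs gating}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(iksgating)
```

## The model

KCNQ1 (Kv7.1) is a voltage-gated potassium channel whose four
voltage-sensing domains (VSDs) each move through two resolvable steps:
resting (R) to intermediate (I), then intermediate to activated (A). The
pore is either closed (C) or open (O), and — unlike classical Shaker-style
schemes — it may open with the VSDs in *any* combination of states. What
couples the two modules is a set of state-dependent interaction energies:
for every pairing of a VSD conformation X ∈ {R, I, A} with a pore state
P ∈ {C, O} there is a dimensionless coupling strength θ_XP. A value
θ_XP > 1 stabilises channel states that combine X with P and therefore
slows every transition that leaves such a state. The reference point of
these couplings is the fully decoupled channel: the intrinsic rates are
what one would measure if VSD and pore did not interact at all.

Because the four VSDs are identical and non-cooperative, a channel state
is fully described by the pore state plus the counts (n_R, n_I, n_A) of
VSDs in each conformation. That gives 15 count combinations × 2 pore
states = 30 channel states (`enumerate_states()`), against 3⁴ × 2 = 162
for labelled VSDs; the aggregation is exact and is verified against an
independently coded 162-state model in the test suite.

VSD transition rates are exponentially voltage dependent,

> k(V) = k⁰ · exp(z F V / R T),

with k⁰ the rate at 0 mV and z a signed equivalent valence; pore rates
k_CO and k_OC carry no voltage dependence. Off-diagonal entries of the
30×30 generator (`build_rate_matrix()`) are:

* VSD step X→Y with pore state P: `n_X · k_XY(V) / θ_XP`;
* pore opening: `k_CO / (θ_RC^n_R · θ_IC^n_I · θ_AC^n_A)`;
* pore closing: `k_OC / (θ_RO^n_R · θ_IO^n_I · θ_AO^n_A)`.

Dividing each departure rate by the couplings of the state being left is
the one structural choice the scheme's description leaves open for the VSD
transitions (it states the division explicitly only for the pore). We
adopt it because it is the minimal rule that (i) makes every θ > 1 a pure
stabilisation — "slows transitions away from" the stabilised state — and
(ii) gives detailed balance around every cycle of the graph, so the scheme
is thermodynamically consistent without tuning. The Kolmogorov cycle
criterion is asserted to 1e-10 over a fundamental cycle basis in the
tests. A consequence of reversibility is a closed-form stationary
distribution (`equilibrium_distribution()`): Gibbs weights

> w = multinom(4; n_R, n_I, n_A) · K_RI(V)^(n_I+n_A) · K_IA(V)^(n_A) ·
> K_CO^[open] · Π θ_XP^(n_X),

with K_xy the equilibrium constants of the component transitions. Weights
are evaluated in log space so extreme voltages cannot overflow; an
SVD-based nullspace solve of the generator is provided as an independent
cross-check (`method = "nullspace"`).

There is a gauge degeneracy worth knowing about: multiplying all three
closed-state couplings by a constant is indistinguishable from rescaling
k_CO (and likewise for the open side and k_OC). The shipped configuration
fixes θ_RC = θ_RO = 1, i.e. the resting VSD is the coupling reference.

## Simulation and observables

`simulate_protocol()` integrates the master equation under
piecewise-constant voltage protocols. Within a segment the solution is the
exact matrix exponential of the segment generator. Because the chain is
reversible, D^{1/2} Q D^{-1/2} (D = stationary distribution) is symmetric,
so the exponential comes from a symmetric eigendecomposition — fast and
stable for the 30×30 problem. When the symmetrised matrix is not
numerically symmetric (stationary weights spanning too many orders) or the
reconstruction leaves negatives beyond −1e-9, the segment is recomputed by
scaling-and-squaring (`Matrix::expm`) stepped sample to sample. The
rate-law exponent is capped at ±700 with a warning; occupancies are
clamped at zero and renormalised only within 1e-9, anything worse aborts
with the offending segment named.

Observables (`observables()`) follow the standard two-electrode
voltage-clamp reading: open probability is the summed open-block
occupancy, current is ohmic, `I = N · g_ion · P_open · (V − E_rev,ion)`,
and fluorescence is the per-VSD label signal
`Σ P(state) (n_I f_I + n_A f_A)/4`. The defaults f_I = 0.8, f_A = 1 make
the first VSD step carry most of the optical signal, as in the
experiments; the second step adds the rest.

`steady_state_curves()` builds conductance–voltage (GV) and
fluorescence–voltage (FV) relations two ways: the `"pulse"` route
replicates the experimental procedure (equilibrate at −80 mV, pulse, take
the instantaneous tail current / end-of-pulse fluorescence, normalise to
the highest test voltage), and the `"equilibrium"` route evaluates the
infinite-pulse limit analytically. Their agreement on the baseline
parameter set — to 1e-8 with 15 s pulses — is itself a test. Pulse-route
points whose open probability still drifts by more than 1e-4 (relative)
over the final 5% of the pulse are flagged `equilibrated = FALSE` rather
than silently trusted; with strong intermediate-closed stabilisation the
activation path slows ~20-fold and 4-s pulses genuinely do not
equilibrate, which is why the KCNE1 comparison below uses the equilibrium
route by default.

## Default parameters

The parameter tables this model family was originally fitted with are not
available as machine-readable values, so the shipped baseline
(`default_kcnq1()`, also in `inst/extdata/default_kcnq1.yaml`) is the
package's own calibration, chosen once to reproduce the qualitative
KCNQ1 phenotype and then left alone:

| parameter | value | rationale |
|---|---|---|
| kRI, kIR | 60/s (z +0.6), 5/s (z −0.8) | fast first VSD step, midpoint ≈ −46 mV |
| kIA, kAI | 0.8/s (z +0.4), 2.0/s (z −0.5) | slow second step, midpoint ≈ +26 mV |
| kCO, kOC | 2/s, 700/s | intrinsically reluctant pore (K_CO ≈ 0.003) |
| θ_IO | 3 | intermediate-open stabilisation: the channel opens from intermediate VSDs, so the GV tracks the low-voltage FV component |
| θ_AO | 3.5 | keeps P_open monotone in V with maximal P_open ≈ 0.3, leaving severalfold headroom for open-state stabilisation |
| others θ | 1 | resting-state reference gauge |

Voltages are mV everywhere at the interfaces (converted to volts inside
the rate law), rates s⁻¹, times ms; F = 96485.332 C/mol,
R = 8.31446 J/(mol·K), T = 298.15 K by default and configurable.

## The in-silico KCNE1 experiment

KCNE1, the accessory subunit that converts KCNQ1 into the cardiac IKs
current, is modelled purely as a perturbation of two couplings
(`kcne1_perturbation()`): θ_IC × 20 (the intermediate-closed state is
stabilised, so the pore no longer opens from intermediate VSDs) and
θ_AO × 5 (the activated-open state is stabilised). Every intrinsic rate is
bit-identical between baseline and perturbed sets — the point of the
exercise is that coupling changes alone reproduce the phenotype. The
factor magnitudes are package defaults chosen so the signatures trigger
robustly; the directions are fixed by the biology.

`signature_report()` quantifies five signatures; on the shipped baseline
the canonical perturbation yields a +92 mV GV shift with reassignment of
the GV from the main (low-voltage) to the high FV component, a −54 mV
shift of the main FV component, an onset delay growing from 15 ms to
about 1.1 s at +40 mV, and a 3.3-fold rise in maximal steady-state
current. Flags use resolvability deadbands — 5 mV for midpoint shifts,
10 ms for the delay, 5% for the fold change — because two-component
Boltzmann fits jitter by a couple of millivolts even on noiseless model
curves; a "shift" smaller than that is not a signature. The contrast case
(weakening θ_IO instead of strengthening θ_IC, keeping θ_AO × 5)
reproduces the first four signatures but cannot left-shift the main FV
component, which is exactly what distinguishes the two mechanisms.

`recover_perturbation()` closes the loop: given normalised GV/FV tables it
fits the chosen coupling factors (log-scale L-BFGS-B, all k fixed,
confidence intervals from the residual curvature, near-singular curvature
reported as non-identifiable). Noiseless tables return the generating
factors to well under 5%; with 2% Gaussian noise on the tables the factors
come back within 20% across seeded replicates, and deliberately fitting
the wrong coupling (θ_RO) leaves an order-of-magnitude larger residual.

## Synthetic recordings

`generate_recording()` emulates the acquisition chain of a two-electrode
voltage-clamp fluorometry rig: 1 kHz sampling, fluorescence low-pass
filtered at 200 Hz, independent additive Gaussian noise per channel, and a
raw fluorescence intensity built from a baseline with slow linear bleach
(−0.5%/s) plus the physiological signal scaled to a 10% maximal ΔF/F.
The filter is a zero-phase second-order Butterworth applied over
odd-reflection padding — a deliberate deviation from a causal analog
filter, chosen so that filtering does not bias fitted time constants.
Noise magnitudes (1% of maximal current, 2% of maximal fluorescence
deflection by default) are calibration choices, not measured values. All
randomness flows from one integer seed; families derive per-recording
seeds deterministically, and generation is bit-reproducible.

Experiment designs (`experiment_design()` / `generate_experiment()`)
bundle the protocols used throughout: the VCF family (4 s pulses over 13
voltages from −120 to +120 mV, +60 mV tails), the ion-substitution
tail protocol (+60 mV for 5 s, −60 mV tails for 3 s) in which Rb⁺/K⁺
permeation differences are represented as a conductance ratio with the
reversal potential moved to 0 mV — the high-external-permeant-ion
condition of the real experiment, which also gives the tails a driving
force comparable to the pulse so tail noise is not disproportionate — and
an XE991 dose series in which block is phenomenological: drug current =
control current × (1 − f(c)·(1 − e^{−t/τ_block})), f(c) = f_max·c/(c+IC50)
with Hill coefficient 1, τ_block = 700 ms mimicking the slow development
of block. Each experiment ships a ground-truth manifest so that recovery
tests never peek at internal state.

What the generator does **not** emulate: endogenous oocyte currents,
series resistance, leak and capacitive transients, labelling efficiency,
photobleaching beyond a linear baseline, or any mechanistic model of drug
binding. Passing round-trip tests therefore shows estimator correctness
under clean, well-specified conditions — not robustness to every artifact
of a real rig.

## Analysis procedures

* **ΔF/F** (`delta_f_over_f()`): a line is fitted to the 2 s of raw
  fluorescence preceding the pulse at the holding potential, extrapolated
  over the sweep, and the relative deviation from it is returned. A
  constructed drift-times-signal trace is inverted to 1e-6 pointwise.
* **Instantaneous tail amplitude** (`tail_amplitude()`): mono-exponential
  plus offset over a 20–300 ms post-step window, extrapolated to the step
  time. The fit uses variable projection (linear in offset and amplitude,
  1-D profile over τ) with a Levenberg–Marquardt polish, which needs no
  starting guess and is exact to 1e-9 on noiseless tails; a failed fit
  falls back to the first post-step sample and says so.
* **GV/FV extraction** (`extract_gv()`, `extract_fv()`): per-recording
  tail amplitudes / end-of-pulse ΔF/F, normalised to the highest test
  voltage (not the maximum — a distinction that matters when curves are
  non-monotonic).
* **Boltzmann fits** (`fit_boltzmann()`): one or two components of
  `a/(1+exp(−zF(V−V½)/RT))`. Two-component fits run from 8 deterministic
  starts over midpoint/valence grids; best residual wins, ties break
  toward the lower main-component midpoint; the lower-V½ component is
  always labelled "main".
* **Exponential kinetics** (`fit_exponentials()`,
  `select_exponential()`): onset and decay forms, deterministic τ
  multistarts, fast component first, degenerate traces flagged instead of
  fitted, and an extra-sum-of-squares F-test at α = 0.01 for automatic
  mono-vs-bi selection.
* **Permeability ratio** (`permeability_ratio()`): the ratio of
  instantaneous tail amplitudes in Rb⁺- vs K⁺-based solutions. This is
  deliberately the experimental proxy — a tail-amplitude ratio — not a
  flux-equation permeability.
* **Dose response** (`dose_response()`, `fraction_inhibited()`): Hill fit
  with the coefficient fixed at 1.

## Test conditions and their sizes

The suite generates everything it needs at run time. Problem sizes were
chosen to keep the full suite under a minute while leaving the statistical
assertions meaningful: 10 random parameter draws for the
microstate-equivalence check, 50 for thermodynamic consistency, 20 seeded
replicates for each noisy-estimator recovery, 10 for noisy
coupling-factor recovery. Estimator tests use 5 mV voltage grids (49
points), 1% noise for fits of normalised curves, 0.5% for tail-current
work, and 2% for the coupling-recovery tables. The dose–response replicate
suite averages 6 simulated measurements per concentration before fitting,
mirroring how experimental dose tables average several cells; single
measurements at 1% noise leave the IC50 only ~20%-determined with five
concentrations, which is a property of the design, not of the fitter.

## Known limitations

* No inactivated states, subconductance levels, or PIP₂-occupancy states;
  all open states share one conductance.
* No VSD–VSD cooperativity; aggregation relies on it.
* Ohmic driving force only — no GHK flux; ion conditions differ only in
  conductance and reversal potential.
* The coupling-recovery fit assumes the intrinsic rates are known; it
  quantifies identifiability of the coupling factors, not of the full
  model.
* Baseline parameters are a calibration, not estimates; quantitative
  magnitudes (shift sizes, fold changes) depend on them even though the
  directional signatures are robust.
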