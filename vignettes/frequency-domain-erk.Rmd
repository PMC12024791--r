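---
title: "A frequency-domain view of the growth-factor-driven ERK pathway"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A frequency-domain view of the growth-factor-driven ERK pathway}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(erkfreq)
```

## The model

`erkfreq` analyses the PC12-cell ERK pathway model of Ryu and colleagues
(Mol Syst Biol 2015, "Model 1"): a ligand (EGF through EGFR, or NGF
through TrkA) activates its receptor, and activity propagates down the
Ras–Raf–MEK–ERK cascade as four activation/inactivation cycles. Three
regulators close the loops:

* **NFB**, an unidentified negative-feedback protein: activated by ERK\*
  in a receptor-gated manner (`R*² / (K3R² + R*²)`), it shuts down Raf
  activation through the Hill gate `KNFB² / (KNFB² + NFB*²)`.
* **DUSP**, in two tiers: ERK\* induces the transcript `dusp`
  (`ERK*² / (Kdusp + ERK*²)`), which matures into the protein `DUSP` that
  dephosphorylates ERK\*. Both tiers turn over with half-life time
  constants `Tdusp = TDUSP = 90 min`, making this the slowest feedback in
  the network.
* **PFB**, a positive-feedback protein: phosphorylated by ERK\* together
  with active receptor, it re-activates Raf at rate `kPFB` — which is
  zero under EGF and `0.75/60 s⁻¹` under NGF. This single parameter is
  the entire EGF/NGF distinction and underlies the transient-vs-sustained
  dichotomy of ERK activation in PC12 cells.

The state is sixteen dimensionless species: seven (inactive, active)
pairs — R, Ras, Raf, MEK, ERK, NFB, PFB — plus `dusp` and `DUSP`. Each
pair's sum is conserved; we set every total to 1 so that all activities
are fractions, consistent with the dimensionless saturation constants of
the rate table. The basal state is fully inactive with
`dusp = DUSP = duspbasal`, their fixed point at zero ERK\*; with no
ligand this state is an exact equilibrium. Ligand is measured in units of
the receptor dissociation constant Kd (`k1R = kd1R`, so a dose of 1 Kd
gives half receptor occupancy at steady state). The phosphatases
(PtaseR, PtaseRaf, PtaseMEK, PtaseNFB, PtasePFB) and GAP are constant
abundances folded into the parameters, not states.

Two Michaelis denominators in this model family are typeset ambiguously
in the literature. We resolved both against the model's documented
steady-state behaviour: the Raf activation flux saturates in its
substrate (`Raf / (K5 + Raf)`), while the MEK dephosphorylation term
saturates in *inactive* MEK (`MEK* / (D4 + MEK)`). With these readings
the equilibrium ERK\* levels across dose reproduce the reference values
(0.076, 0.110, 0.161 at 0.012, 0.02, 0.04 Kd; 0.235 at 0.315 Kd); the
alternative readings miss them by 30–60%. The dusp induction denominator
is implemented literally as `Kdusp + ERK*²`; a `dusp_hill_squared` switch
provides the `Kdusp² + ERK*²` variant for sensitivity analysis (it
roughly halves low-dose ERK\* and is clearly inconsistent with the
reference equilibria).

## Steady states and dose–response

`solve_equilibrium()` finds roots of the rate equations by damped Newton
iteration in reduced coordinates: one active fraction per conserved pair
plus the two DUSP tiers, nine unknowns. Working in the reduced space
removes the seven structural zero eigenvalues from the Newton Jacobian,
which is computed by complex-step differentiation (step `1e-100`; the
rate laws are rational, so the complex step is exact to machine
precision). Steps are box-damped so activities stay within `[0, total]`,
and convergence is declared below a residual max-norm of `1e-11` —
comfortably inside the `1e-9` precondition used by the linearization.

Without a starting guess the solver continues the branch from the basal
state in ten dose steps; `dose_response()` chains equilibria along a dose
grid the same way (default: 60 log-spaced doses over 0.001–2.5 Kd). This
always reports the branch reachable from the resting cell. An optional
`probe_multistability` re-solves each dose from a strongly activated
guess and flags disagreements; on the default grids both ligand modes are
single-valued. Equilibria are validated against the t → ∞ limit of stiff
integration of the full model (agreement to `1e-6` or better).

The EGF curve rises, plateaus near 0.25 Kd and then declines — the
classic negative-feedback-amplifier signature, since feedback strength
grows with input. Under NGF the decline is much weaker (−13% from peak
to 2.5 Kd, versus −35% for EGF) because positive feedback props up Raf;
the model keeps a slight decline rather than a perfectly flat plateau.

## Linearization and the minimal transfer function

`linearize()` evaluates the Jacobians `A = ∂F/∂x`, `B = ∂F/∂u` at the
equilibrium by complex step; the output is ERK\*, so `C` is a selector
row and `D = 0` exactly. `to_transfer_function()` reduces
`T(s) = C (sI − A)⁻¹ B` to coprime polynomials in three steps:

1. **Structural deflation.** The seven conservation laws contribute
   eigenvalues at the origin that are uncontrollable/unobservable;
   `T(s)` has no pole at zero, so these factors cancel exactly and are
   removed by eigenvalue magnitude (`|λ| < 1e-9` of the spectral
   radius).
2. **Modal cancellation.** A remaining mode is dropped only if it cannot
   appear in the input–output map: `|C v| < cancel_tol` or
   `|w B| < cancel_tol · |B|` for its unit right/left eigenvectors. Under
   EGF the PFB pair feeds nothing back (`kPFB = 0`), so its mode is
   exactly unobservable (`|C v| ~ 1e-17`) and cancels; under NGF it does
   not. We deliberately do *not* cancel by pole–zero distance: at low
   receptor occupancy the weakly coupled NFB mode carries a genuine
   pole–zero pair separated by as little as `1e-11` of the spectral
   radius, so any distance threshold either destroys that mode or misses
   the exact cancellation. The modal test separates the two cases by
   thirteen orders of magnitude; the default `cancel_tol = 1e-8` sits in
   the middle of that gap.
3. **Numerator recovery.** `T(s) · Π(s − p_kept)` is a low-degree
   polynomial. It is evaluated at 64 points on a complex circle (radius:
   geometric mean of the retained pole magnitudes) via resolvent linear
   solves, and its coefficients are recovered by FFT interpolation —
   perfectly conditioned on a uniform circle, with no symbolic
   determinant expansion anywhere. Roots give the zeros; the leading
   coefficient gives the gain.

The reduced form is verified against direct resolvent evaluation before
being returned (observed agreement ~`1e-13`; the constructor aborts above
`1e-7`). For EGF at any interior dose the result is degree 3 over degree
8 — with the monic denominator, 13 coefficients in place of 16 states and
38 rate constants. Under NGF the PFB mode is part of the minimal system
and the orders grow to (4, 9). The orders are discovered, not assumed.

## Bode conventions

`frequency_response()` evaluates `T(iω)` by one 16×16 linear solve per
frequency — the factored rational form is available but the resolvent
route has no cancellation error at any dose. The phase is unwrapped
continuously from the low-frequency end and then anchored at the
high-frequency asymptote implied by the relative degree: five poles
beyond the zeros give `−450°` (plus 180° if the leading Markov parameter
is negative). Anchoring makes the low-frequency phase land in
`[0°, 360°)` and resolves the 360° ambiguity that raw unwrapping leaves:
under NGF at 0.25 Kd the low-frequency phase is 360°, not 0°, because
the sweep loses 810° in total (two right-half-plane zeros add 360° to
the minimum-phase 450°).

The default grid is 100 points per decade over `1e-6`–`1e2` rad/s. The
upper limit matters: the fastest pathway eigenvalue is ~0.12 s⁻¹, so at
1 rad/s the phase is still ~10° short of its asymptote; two more decades
let the total phase change converge to within a fraction of a degree.
`bode_metrics()` reports the peak modulation (warning if it sits on a
grid boundary), the total unwrapped phase change across the sweep, and
the low-frequency phase.

At 0.01 Kd the pathway is a low-pass amplifier: gain ~9.6 with a mild
resonance near `2.5e-4` rad/s, phase starting at 0° and falling 450°. By
0.5 Kd it is a suppressor: gain < 1 everywhere with a 180° low-frequency
phase — output fluctuations oppose input fluctuations, as in any strong
negative-feedback loop. In this implementation the peak modulation
crosses unity at ≈0.135 Kd; qualitative accounts of this model place the
crossing somewhat higher (0.2–0.5 Kd), and we note the crossing location
is sensitive to the low-dose gain of the cascade while the flanking
behaviours (amplifier at ≤0.1 Kd, suppressor at ≥0.2 Kd) are robust.

## Periodic forcing

A periodic ligand waveform `f(t)` with period `T` enters through its
Fourier series `a0/2 + Σ an cos(2πnt/T) + Σ bn sin(2πnt/T)`. The closed
forms are exact: for a rectangular train of amplitude `A` and width `τ`,
`a0/2 = Aτ/T`, `an = (A/πn) sin(2πnτ/T)`, `bn = (A/πn)(1 − cos(2πnτ/T))`;
for a triangle of peak `A`, mean `A/2` and odd cosine harmonics
`−4A/((2n−1)²π²)`. Both are unit-tested against composite Gauss–Legendre
quadrature to `1e-10`.

`forced_response()` maps the mean through the *nonlinear* equilibrium at
constant dose `a0/2` and each harmonic through `M(ωn)`, `φ(ωn)` evaluated
at that equilibrium — the standard small-signal superposition. The
output is exactly periodic, so metrics are taken over one cycle:
`equilibrium_level` (the baseline), `peak` (cycle maximum) and
`gain_modulation = peak / equilibrium_level`. Pulse-frequency protocols
follow the "n pulses per hour" convention, `T = 3600/n` s with a fixed
180 s pulse width, so the three reference protocols (3, 5, 10 pulses/h)
have means 0.012, 0.02 and 0.04 Kd at `A = 0.08`. Defaults of 200
harmonics (rectangular) and odd harmonics up to 199 (triangular) leave
the metrics converged to well under 0.5% (doubling changes them by
~`1e-11`; the harmonics beyond ~50 are annihilated by the ω⁻⁵
roll-off anyway). Waveform constructors reject non-physical geometries
(`tau` outside `(0, T)`, sinusoid amplitude exceeding its mean).

Because the reconstruction is linear about the mean, its fidelity is
bounded by the perturbation size. At `A = 0.08` Kd the low-frequency
train still swings the output to −0.02 at the trough (a Gibbs-plus-
linearization artifact: true ERK\* cannot be negative); at `A = 2.1` Kd
the reported peak underestimates what the full nonlinear model would do.
This is intrinsic to the transfer-function approach, which is designed
for small perturbations around an equilibrium; `crosscheck_linearization()`
quantifies the error explicitly (below).

## The nonlinear oracle

`simulate_pathway()` integrates the full model with `deSolve::lsoda`
(default `rtol 1e-10`, `atol 1e-12`), restarting the integrator at input
discontinuities so steps and pulse edges are resolved exactly. It
validates three things:

* **Conservation and positivity.** Pair sums drift by < `1e-8` and
  states stay above `−1e-9` along all tested trajectories.
* **Step responses.** From the basal state, a 1 Kd step of EGF drives
  ERK\* to a peak at ~8 min that decays to ~27% of peak in an hour;
  the same NGF step holds ~77% — the transient/sustained dichotomy that
  distinguishes proliferative from differentiative signalling. The
  precise 1-hour fractions depend on dose (EGF falls to 15–18% at
  saturating doses; NGF holds 82–88% below 0.5 Kd), so we treat them as
  qualitative dose-robust signatures rather than sharp constants.
* **Linear-regime validation.** `crosscheck_linearization()` drives the
  nonlinear model with a small sinusoid about a mean dose, starts at the
  equilibrium, verifies cycle-to-cycle settling, extracts the
  fundamental by least-squares sine/cosine fit over four cycles, and
  compares amplitude and phase with `M`, `φ`. At amplitude `1e-3` of the
  mean the error is ~`7e-6`; it grows quadratically with amplitude
  (nonlinearity) and stays below 1% even at 10% relative amplitude near
  `1e-3` rad/s.

## What the synthetic inputs do and do not emulate

The waveform generator produces the idealized stimulation protocols of
microfluidic experiments: sharp-edged rectangular pulse trains,
symmetric triangles, exact sinusoids, all noiseless and perfectly
periodic. Real perfusion systems have finite exchange times (~seconds),
ligand depletion and receptor internalization, none of which are in the
model; cell-to-cell variability and stochastic receptor-level noise are
likewise absent. Passing tests therefore demonstrate the deterministic
filtering properties of this reaction network, not quantitative
predictions for any particular experimental rig.

## Numerical choices, degenerate inputs, limitations

* Complex-step differentiation everywhere a Jacobian is needed (Newton
  solver, linearization); finite differences appear only as an
  independent oracle in the tests.
* Newton steps are damped by halving (up to 40 times) and clipped to the
  physical box; a singular Jacobian is ridge-regularized at `1e-12`.
  Non-convergence raises an error carrying the dose and final residual.
* `bode_metrics()` refuses grids that do not span `1e-6`–`1` rad/s;
  `frequency_response()` refines internally (with a warning) if adjacent
  principal phases ever jump by more than 90°.
* Scenario outputs round to 6 significant digits, making reruns
  byte-identical; scenario and CLI configuration parsing is strict —
  unknown keys or scenario names are fatal, never ignored.
* Parameter files are flat `key = value` text with the rate-constant
  symbols as keys; bundled defaults for both ligand modes live in
  `inst/extdata/`.
* Known limitations: amplitudes far above the linear regime (the 2.1 Kd
  and 4.2 Kd protocols) are reconstructed with ~10–15% peak error by
  construction; the amplifier→suppressor crossing dose and the exact
  1-hour step-response fractions are model-sensitive as discussed above;
  no stochastic or spatial variants; no parameter fitting.
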