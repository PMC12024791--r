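# erkfreq

Frequency-domain analysis of the growth-factor-driven ERK signalling
cascade.

Cells rarely see constant growth-factor levels: microfluidic and
optogenetic experiments deliver EGF or NGF to PC12 cells as pulse trains,
ramps and waves, and the shape of the resulting ERK activation decides
between proliferation and differentiation. `erkfreq` treats the ERK
pathway as a signal-processing filter. It implements the 16-state ODE
model of the PC12 ERK cascade of Ryu and colleagues — receptor, Ras, Raf,
MEK and ERK activation cycles with an ERK-induced negative feedback
protein, a two-tier DUSP negative regulator, and (under NGF) a positive
feedback protein — and asks how that network transforms periodic ligand
inputs into periodic ERK\* outputs.

The pipeline is the classical control-theoretic one:

1. **Steady states.** For a constant ligand dose `u` (in units of the
   receptor dissociation constant Kd), solve `F(x, u) = 0` by damped
   Newton iteration in the 9 coordinates left free by the seven
   conservation laws, continuing the branch from the resting cell.
2. **Linearization.** At the equilibrium `(x_e, u_e)` compute the Jacobian
   state-space system `dx/dt = A x + B u`, `y = C x` (output: ERK\*;
   feedthrough `D = 0`), with complex-step derivatives exact to machine
   precision.
3. **Transfer function.** Reduce `T(s) = C (sI − A)^{-1} B` to a minimal
   rational form by cancelling uncontrollable/unobservable modes. For the
   EGF map this yields a cubic over an octic,

   `T(s) = (a1 s³ + a2 s² + a3 s + a4) / (s⁸ + b2 s⁷ + … + b9)`,

   13 coefficients summarizing 16 states and 38 rate constants.
4. **Bode analysis.** Modulation `M(ω) = |T(iω)|` and continuously
   unwrapped phase `φ(ω) = arg T(iω)` over a log-frequency grid. Low
   receptor occupancy makes the pathway a low-pass *amplifier* (gain ≈ 10,
   phase 0° at low frequency); high occupancy makes it a *suppressor*
   (gain < 1, phase 180°, the negative-feedback regime).
5. **Periodic forcing.** Decompose rectangular/triangular pulse trains or
   sinusoids into Fourier series, map the mean through the nonlinear
   equilibrium and each harmonic through `M` and `φ`, and reconstruct the
   periodic ERK\* response with its summary metrics (equilibrium level,
   cycle peak, gain modulation = peak/equilibrium).

A stiff nonlinear integrator (`deSolve`) provides ground truth throughout:
equilibria are cross-checked against long integrations, and the linearized
frequency response is validated against small-amplitude sinusoidal
simulations of the full model.

## Worked example

```r
library(erkfreq)

p  <- pathway_params("EGF")              # Ryu-model rate constants, EGF mode
eq <- solve_equilibrium(p, 0.012)        # steady state at 0.012 Kd ligand
eq
#> ERK pathway equilibrium (EGF, dose 0.012 Kd): ERK* = 0.075766, residual 8.05e-16, stable

ss <- linearize(eq)
tf <- to_transfer_function(ss)
tf
#> Rational transfer function EGF -> ERK* at dose 0.012 Kd: degree 3 / 8 (13 coefficients)
#>   T(0) = 5.10044

bode_metrics(frequency_response(ss))
#> $peak_modulation        9.8
#> $omega_peak             0.000245
#> $total_phase_change_deg 450
#> $low_freq_phase_deg     0.365

spec <- pulse_train_spec("rectangular", A = 0.08, T = 1200, tau = 180)
forced_response(fourier_rectangular(spec), baseline_eq = eq)
#> Periodic ERK* response (EGF, mean dose 0.012 Kd, period 1200 s):
#>   equilibrium 0.07577, peak 0.2436, gain modulation 3.22
```

Reading: at 1.2% receptor occupancy the pathway amplifies slow input
fluctuations almost tenfold, in phase, and loses 450° of phase across the
sweep — the signature of a five-step kinetic chain with negligible
feedback. Pulsing 0.08 Kd of EGF for 3 minutes every 20 minutes therefore
yields ERK\* spikes to 0.24 over an equilibrium of only 0.076: a gain
modulation above 3.

The scenario layer regenerates every figure-level analysis as
deterministic CSV/JSON reports:

```r
run_scenario("fig4_dose_response", "out/")   # see erkfreq_scenarios()
```

or from a shell via the bundled CLI:

```sh
Rscript inst/cli/erkfreq.R bode --ligand egf --dose-kd 0.01 --out-dir out/
```

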