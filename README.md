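# nocithresh

Hazard-model simulation of nociceptive detection thresholds for
electrocutaneous stimulation.

## The problem

Psychophysical detection thresholds for weak intra-epidermal electrical
stimuli are mediated by Aδ fibers and shaped by both peripheral (skin,
nerve endings) and central (dorsal horn) processing. When an intervention —
for example a high-dose topical capsaicin treatment — changes several of
these subsystems at once, the measured threshold changes alone cannot
separate the contributing mechanisms. `nocithresh` implements a compact
neurophysiology-based forward model that makes this separation possible in
simulation, for researchers in pain psychophysics and computational
neuroscience.

## The model

A stimulus is a square-wave pulse train with amplitude *A* (mA), pulse
width *PW* (ms), pulse count *NoP* and interpulse interval *IPI* (ms).
The stages are:

1. **Peripheral activation.** A pulse of finite width acts with effective
   amplitude *f<sub>A</sub>* = *A* (1 − e^(−PW/τ₁)); the afferent
   population drive is threshold-linear, π\[*f<sub>A</sub>* − α₁\]₊.
2. **Synaptic current.** Each pulse injects an exponential postsynaptic
   current with time constant τ<sub>s</sub> = 1.5 ms.
3. **Membrane integration.** A dorsal-horn neuron integrates the current as
   a leaky integrator with time constant τ₂ (temporal summation across
   pulses); the package uses the closed-form solution.
4. **Stochastic spiking.** Spikes form a non-homogeneous Poisson process
   with sigmoidal rate λ(t) = λ_L / (1 + exp((α_L − x(t))/σ_L)).
5. **Detection.** The stimulus is detected iff at least one spike occurs in
   the trial window, so the psychometric function is
   Ψ(*A*) = 1 − exp(−∫λ dt), and the detection threshold *A₅₀* solves
   Ψ(*A₅₀*) = 0.5.

On top of the forward model the package provides:

* a closed-form threshold theory for double-pulse stimuli in the
  τ<sub>s</sub> → 0, σ_L → 0 limit, including the three supra-threshold
  crossing geometries, the case-switch intervals *IPI₂₁*/*IPI₂₃*, and the
  monotonicity condition λ_L τ₂ ≶ 1 for the threshold-versus-IPI curve;
* a multiplicative map from fifteen physical quantities (fiber density,
  ending depth, membrane properties, synaptic gain, ...) to the six lumped
  model parameters, with single-parameter threshold sweeps and
  monotonicity classification;
* a five-day topical-capsaicin scenario (degeneration, peripheral and
  central sensitization as per-day ratio patterns) with ablation variants;
* a synthetic psychophysics generator (Bernoulli responses from Ψ) and a
  maximum-likelihood threshold-recovery harness.

## Worked example

Reference detection thresholds for the four standard stimulus
combinations:

```r
library(nocithresh)
threshold_table()
#>   NoP IPI_ms PW_ms A50_mA psi_at_A50 solver_iterations
#> 1   1     NA 0.210 0.6099        0.5                 7
#> 2   1     NA 0.525 0.4274        0.5                 7
#> 3   2     20 0.525 0.2514        0.5                10
#> 4   2     50 0.525 0.2534        0.5                 6
```

Double pulses summate temporally, so their thresholds (~0.25 mA) are far
below the single-pulse ones; `psi_at_A50 = 0.5` confirms each solve closed
its defining equation. The closed-form limit theory gives nearly the same
double-pulse threshold and identifies the crossing geometry:

```r
a <- analytic_threshold(PW = 0.525, IPI = 20, params = lumped_params(), NoP = 2)
round(as.numeric(a), 6); attr(a, "case")
#> [1] 0.252153
#> [1] "SPANNING_INTERVAL"
case_boundaries(45, 0.01)
#> $IPI21: -58.46098   $IPI23: 24.33211
```

With the reference λ_L τ₂ = 0.45 < 1, the threshold-versus-IPI curve is
non-monotone with its interior minimum at *IPI₂₃* ≈ 24.3 ms. The capsaicin
scenario reproduces the observed dissociation — on Day 2 the single-pulse
threshold rises ~11% while the 20-ms double-pulse threshold barely moves —
and the slow recovery of double-pulse thresholds:

```r
run_study(variants = "FULL", combos = standard_combos()[c(1, 3)])
#>    day NoP IPI_ms A50_mA pct_change_vs_day0
#> 1    0   1     NA  0.610              0.000
#> 3    2   1     NA  0.675             10.670
#> 4    2   2     20  0.254              0.884
#> 6    7   2     20  0.317             26.226
#> 8   28   2     20  0.296             17.938
#> 10  84   2     20  0.280             11.325
```

(abridged; `pattern_check()` asserts the full qualitative pattern.)

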