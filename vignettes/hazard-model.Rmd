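---
title: "The hazard model of nociceptive detection: methods and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The hazard model of nociceptive detection: methods and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nocithresh)
```

## The model and its assumptions

`nocithresh` simulates Aδ-fiber-mediated detection of intra-epidermal
electrocutaneous pulse trains. The model chain is deliberately minimal:

* **Afferent activation is instantaneous and threshold-linear.** A square
  pulse of width $PW$ charges the nerve-ending membrane (time constant
  $\tau_1$) towards the stimulus amplitude $A$, so it is equivalent to an
  instantaneous pulse of effective amplitude
  $f_A = A\,(1 - e^{-PW/\tau_1})$. The population drive is
  $\pi [f_A - \alpha_1]_+$; the factor $\pi$ arises from the radial
  recruitment geometry of nerve endings around the electrode and is kept
  exactly. Each pulse evokes at most one afferent spike (valid for the
  sub-millisecond pulse widths used experimentally), and axonal
  propagation is assumed faithful — propagation failures, demyelination
  and T-junction filtering are out of scope.
* **Synaptic and membrane filtering are linear.** Every pulse injects an
  exponential postsynaptic current (time constant $\tau_s$, default
  1.5 ms) into a leaky-integrator membrane (time constant $\tau_2$,
  default 45 ms). Short-term synaptic facilitation/depression is not
  modelled. The postsynaptic potential (PSP) is therefore available in
  closed form: per pulse at onset $t_k$,
  $x(t) = D\,\frac{e^{-(t-t_k)/\tau_2} - e^{-(t-t_k)/\tau_s}}{\tau_2 - \tau_s}$,
  summed over pulses. No numerical ODE integration is used in the
  pipeline; an independent stiff-solver integration serves as a test
  oracle only.
* **Spiking is an inhomogeneous Poisson process** with sigmoidal rate
  $\lambda(t) = \lambda_L \left(1 + e^{(\alpha_L - x(t))/\sigma_L}\right)^{-1}$,
  and a trial is detected iff at least one spike falls in the trial
  window, giving $\Psi(A) = 1 - e^{-\int_0^T \lambda\,dt}$ (probability
  summation). The detection threshold $A_{50}$ solves $\Psi(A) = 0.5$ and
  is well defined because $\Psi$ is nondecreasing in $A$ and
  $\Psi(0) \approx \lambda_L T e^{-\alpha_L/\sigma_L} \ll 0.5$ at the
  reference values.

### Parameters

Units are mA and ms throughout. This makes mA/ms numerically identical to
A/s and events/ms identical to kHz, so the published reference values are
used verbatim with no conversion constants:

| parameter | meaning | reference | unit |
|---|---|---|---|
| $\alpha_1$ | afferent activation threshold | 0.125 | mA |
| $\tau_1$ | afferent membrane time constant | 0.2 | ms |
| $\tau_2$ | dorsal-horn membrane time constant | 45 | ms |
| $\alpha_L$ | central activation threshold | 0.00417 | mA/ms |
| $\sigma_L$ | central slope parameter | 8.33e-5 | mA/ms |
| $\lambda_L$ | maximal population firing rate | 0.01 | events/ms |
| $\tau_s$ | synaptic time constant | 1.5 | ms |

$\sigma_L \ll \alpha_L$ (ratio $\approx$ 1:50), so the rate function is
nearly a step at $\alpha_L$ — which is what makes the closed-form limit
theory below accurate at a few-percent level even for the full model.

## Numerical choices

* **Trial window.** The integration end time is not part of the model
  definition, only that it covers the stimulus; the package uses
  $T = t_{\text{last pulse}} + 15\,\tau_2$ (configurable
  `window_factor`). The PSP has decayed by $e^{-15}$ at $T$, the truncated
  hazard tail is orders of magnitude below the quadrature tolerance, and
  $T$ stays far below the ~3 s inter-stimulus spacing of the experiments
  the model targets. Tests assert that doubling the window leaves the
  expected count unchanged within `quad_tol`.
* **Quadrature.** The integrand $\lambda(x(t))$ is smooth except for kinks
  at pulse onsets, so the expected count uses composite Simpson on panels
  split at every onset, step $\tau_2/200$, refined to $\tau_s/5$ over the
  first $10\,\tau_s$ after each onset where the synaptic rise is steep.
  `quad_step` can override the coarse step; the near-limit convergence
  tests use 0.01 ms because a near-step rate function localises the
  integrand's variation to ~0.03 ms around each threshold crossing.
* **Root solve.** $\Psi$ is monotone in $A$, so the threshold is bracketed
  (upper bound starting just above the rheobase
  $\alpha_1/(1-e^{-PW/\tau_1})$, doubled until $\Psi > 0.5$, error
  `threshold unreachable` past `amplitude_bracket_max`) and solved by
  Brent's method. The solve is polished beyond `root_tol` (to
  `root_tol^2`) so that the defining equation itself closes:
  $|\Psi(A_{50}) - 0.5| \le 10\,$`quad_tol` in the tests.
* **Guards.** The sigmoid underflows harmlessly at reference values
  ($\alpha_L/\sigma_L \approx 50$); for extreme sweeps, exponents above
  700 return rate 0 exactly. The degenerate kernel $\tau_2 = \tau_s$ uses
  the analytic limiting form $s\,e^{-s/\tau_2}/\tau_2^2$ rather than a
  perturbation.

## The closed-form double-pulse theory

In the limits $\tau_s \to 0$ and $\sigma_L \to 0$ the PSP is
$x^0(t) = B \sum_k e^{-(t - k\,IPI)/\tau_2} H(t - k\,IPI)$ with per-pulse
peak $B = \pi[f_A - \alpha_1]_+ / \tau_2$, and the rate is a step, so
$\Psi = 1 - e^{-\lambda_L \Delta T}$ where $\Delta T$ is the total time
above $\alpha_L$. Two conventions deserve note:

* $B$ **divides** the drive by $\tau_2$. This is forced by dimensional
  consistency: $B$ must carry the units of $\alpha_L$ (mA/ms), and it is
  the $\tau_s \to 0$ limit of the double-exponential impulse response
  above. The package's numeric-versus-analytic agreement tests (2% across
  the IPI range) confirm the convention.
* All logarithms are natural: the single-pulse supra-threshold time must
  reduce to the leaky-integrator decay time $\tau_2 \ln(B/\alpha_L)$.

For a double pulse there are three crossing geometries — only upon the
second pulse (`SECOND_PULSE_ONLY`), two separate intervals
(`TWO_INTERVALS`), one spanning interval (`SPANNING_INTERVAL`) — with
closed-form $\Delta T_{1,2,3}$. The threshold solves
$\lambda_L \Delta T = \ln 2$; `analytic_threshold()` tries the
two-interval candidate first and, if its validity inequalities fail,
selects the short-IPI case by the sign of $\lambda_L \tau_2 - 1$. At a
boundary tie the large-IPI case is used; the expressions coincide there,
so the choice is observationally irrelevant (tested to $10^{-9}$ mA).

The case-switch intervals are
$IPI_{21} = -\tau_2 \ln(2^{1/(\tau_2\lambda_L)} - 1)$ and
$IPI_{23} = \tau_2 \ln\!\big(\sqrt{2^{1/(\tau_2\lambda_L)} + 1/4} - 1/2\big)$.
Direct evaluation shows that for $\lambda_L\tau_2 < 1$ it is $IPI_{23}$
that is positive (24.33 ms at reference) and $IPI_{21}$ negative, and
vice versa for $\lambda_L\tau_2 > 1$; the implementation follows the
formulas, which are also the only assignment consistent with the
monotonicity result: for $\lambda_L\tau_2 < 1$ the threshold-versus-IPI
curve falls until $IPI_{23}$ and rises after (an interior minimum), while
for $\lambda_L\tau_2 > 1$ it increases monotonically. Note that on a
discrete IPI grid the argmin can land one grid point to the right of
$IPI_{23}$ because the curve rises much more slowly on the case-2 side
than it falls on the case-3 side.

## Physical-to-lumped parameter mapping

Absolute values of the fifteen physical quantities are not identifiable
from detection data (only six lumped parameters enter the model), so the
package represents perturbations purely as multiplicative ratios with
baseline 1 and maps them through the lumped-parameter expressions:
$\alpha_1 \propto c_0 c_1 G_1 V_{th} h^2$, $\tau_1 \propto C_1/G_1$,
$\tau_2 \propto C_2/G_2$,
$\alpha_L \propto c_0 c_1 G_1 G_2 V_{th}\,\alpha_h /(\rho \bar g K)$
(likewise $\sigma_L$ with $\sigma_h$), $\lambda_L \propto l \lambda_h$.
The exponents are taken exactly as printed in the source expressions
(linear in each factor, $h$ squared); this reproduces all the qualitative
sweep and scenario patterns checked by the tests. Three subgroups are
exactly redundant — $\{V_{th}, c_0, c_1\}$, $\{\rho, \bar g, K\}$,
$\{l, \lambda_h\}$ — and compensating ratios are tested to leave every
threshold unchanged.

Sweeps default to factors 0.60–1.70 in steps of 0.025 (45 points), fine
enough to resolve the shallow extrema of the $C_2/\tau_2$ and
$\sigma_h/\sigma_L$ curves; the acceptance checks use a reduced 15-point
grid, which still resolves the $C_2/\tau_2$ non-monotonicity but leaves
the tolerance-level $\sigma_h$ extremum at $IPI = 30$ ms classified
`FLAT` — that effect is genuinely at the edge of observability.

## The capsaicin scenario

The five study days (0, 2, 7, 28, 84) perturb five ratios: $\rho$ and $h$
(structural degeneration and retraction of nerve endings), $V_{th}$
(peripheral sensitization via neurogenic inflammation, present only on
Day 2 as the inflammation resolves within a few days), and $G_2$, $\bar g$
(central sensitization). The $\rho$ timeline anchors the measured Day-7
(0.21) and Day-84 (0.80) density ratios and inter-/extrapolates linearly
(constant regrowth rate) to Days 28 (0.371) and 2 (0.172); Day 0 is the
off-line baseline.

The ablation variants reset functional ratios to 1 while always keeping
the structural pair $(\rho, h)$ — degeneration is anatomy, not a tunable
gain: `NO_FUNCTIONAL` resets $V_{th}, G_2, \bar g$; `NO_CENTRAL` resets
$G_2, \bar g$; `NO_PERIPHERAL` resets $V_{th}$. The scenario's qualitative
pattern is asserted by `pattern_check()`: single-pulse thresholds rise on
Days 2 and 7; double-pulse thresholds rise on Days 7, 28 and 84; every
ablation variant is at least the FULL threshold on Days 2–28 (functional
plasticity only ever compensates the degeneration-driven rise). The Day-2
near-invariance of the double-pulse threshold is asserted for the
$IPI = 20$ ms combination, where the effect is within 1%; at
$IPI = 50$ ms the model puts the Day-2 change at just under +3%, so a 2%
invariance band would misclassify a real (if small) predicted change —
the dissociation claim is about the 20-ms combination, and that is what
is tested.

## Synthetic psychophysics

`generate_dataset()` emulates the Bernoulli trial structure of a detection
experiment: per trial, $R = 1$ iff a uniform deviate falls below
$\Psi(A)$, over a fixed amplitude ladder. It does **not** emulate adaptive
staircase procedures, lapses/guesses, attentional drift, or inter-trial
dependence — so passing recovery tests demonstrate the estimator and
pipeline are consistent, not that real data will be as clean. Replicate
$i$ of a recovery experiment uses seed $\texttt{seed} + i - 1$; identical
seeds reproduce identical records.

The threshold estimator deserves comment. The model's psychometric curves
are strongly asymmetric: a steep onset just above the rheobase and a
near-logarithmic saturation above threshold (at the reference single-pulse
condition, $\Psi$ is still only ~0.73 at three times $A_{50}$). Generic
symmetric two-parameter fits (logistic/Weibull GLMs in log-amplitude) are
structurally biased upward on such curves — the bias is a property of the
fitted family, not of the data volume, and the test suite demonstrates it
directly by showing the logistic estimate exceeds the generating
threshold even at large trial counts. The default
estimator (`family = "model"`) therefore fits, by maximum likelihood, the
model's own psychometric shape with a single free location shift in
log-amplitude; the location is exactly the log-threshold, and a Wald
interval follows from the observed information. The logistic GLM is kept
as `family = "logistic"` for comparison, and a test documents its bias.

Recovery calibration (100 replicates, 7-level ladder log-spaced over
0.7–1.4 × $A_{50}$, 50 trials/level) uses the 20-ms double-pulse
condition, whose steep curve makes the threshold well determined:
the tests assert relative bias below 2% and at least 95% of replicates
within 5% of the truth. The single-pulse $PW = 0.21$ ms curve is shallow
enough that the binomial information in 350 trials cannot pin the
threshold to a few percent regardless of estimator — a useful design fact
for experimenters choosing stimulus conditions for threshold tracking.

## Problem sizes in the test suite

The tests run the full model end to end at deliberately moderate sizes:
100 random parameter draws for the PSP-versus-ODE oracle, 400 random
draws for the interval-counting brute force, 40-point IPI grids, 15-point
sweep grids over ten physical quantities, the complete
5 days × 4 variants × 4 combinations study, 10,000-trial Monte-Carlo
frequency checks and 100-replicate recoveries. A full threshold solve
takes a few milliseconds, so the entire suite completes in well under a
minute.

## Known limitations

* The model omits axonal propagation, short-term synaptic plasticity and
  C-fiber contributions by design; it addresses near-threshold Aδ
  detection only.
* The closed-form theory covers double pulses; for more pulses the effect
  of temporal summation is analogous but no closed form is provided.
* Physical quantities exist only as ratios; the package deliberately has
  no absolute physical baselines to perturb.
* The capsaicin scenario is a ratio table, not a dynamical model of
  inflammation or regrowth kinetics; days between the tabulated ones are
  only defined for $\rho$ (via the linear timeline).
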