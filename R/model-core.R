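#' Effective stimulus amplitude of a finite-width pulse
#'
#' A square current pulse of width `PW` charges the nerve-ending membrane
#' (time constant `tau1`) to a fraction `1 - exp(-PW/tau1)` of its
#' steady-state value, so a finite pulse acts like an instantaneous pulse of
#' reduced amplitude `fA = A * (1 - exp(-PW/tau1))`.
#'
#' @param A stimulus amplitude, mA (vectorised).
#' @param PW pulse width, ms.
#' @param tau1 afferent membrane time constant, ms.
#' @return The effective amplitude `fA` in mA.
#' @examples
#' effective_amplitude(0.22, PW = 0.525, tau1 = 0.2)
#' @export
effective_amplitude <- function(A, PW, tau1) {
  if (!is.finite(PW) || PW <= 0) stop("'PW' must be positive", call. = FALSE)
  if (!is.finite(tau1) || tau1 <= 0) stop("'tau1' must be positive", call. = FALSE)
  if (any(A < 0)) stop("'A' must be non-negative", call. = FALSE)
  A * (1 - exp(-PW / tau1))
}

#' Peripheral population drive
#'
#' Threshold-linear activation of the afferent fiber population:
#' `pi * (fA - alpha1)` when the effective amplitude exceeds the afferent
#' activation threshold `alpha1`, zero otherwise. The geometric factor `pi`
#' stems from the radial recruitment of nerve endings around the electrode.
#'
#' @param fA effective amplitude, mA (vectorised).
#' @param alpha1 afferent activation threshold, mA.
#' @return Drive `D` in mA.
#' @export
peripheral_drive <- function(fA, alpha1) {
  if (!is.finite(alpha1) || alpha1 <= 0) stop("'alpha1' must be positive", call. = FALSE)
  pi * pmax(fA - alpha1, 0)
}

#' Postsynaptic current of a pulse train
#'
#' Each pulse at onset time `k * IPI` injects an exponential synaptic
#' current `(D / tauS) * exp(-(t - k*IPI)/tauS)`; contributions superpose.
#' The Heaviside gate is closed before each onset and open from the onset
#' itself (the current jumps to `D/tauS` at `t = k*IPI`).
#'
#' @param t time, ms (vectorised).
#' @param stim a [stimulus_train()] supplying `NoP` and `IPI`.
#' @param D peripheral drive, mA (see [peripheral_drive()]).
#' @param tauS synaptic time constant, ms.
#' @return Current in mA/ms.
#' @export
psc <- function(t, stim, D, tauS) {
  stopifnot(inherits(stim, "stimulus_train"), tauS > 0)
  out <- numeric(length(t))
  for (tk in pulse_times(stim)) {
    s <- t - tk
    on <- s >= 0
    out[on] <- out[on] + (D / tauS) * exp(-s[on] / tauS)
  }
  out
}

# Impulse response of the leaky integrator tau2 * x' = -x + Ipsc to one
# synaptic pulse of unit drive: (exp(-s/tau2) - exp(-s/tauS)) / (tau2 - tauS)
# for s >= 0.  For tau2 == tauS the kernel degenerates to the limiting form
# s / tau2^2 * exp(-s/tau2).
psp_kernel <- function(s, tau2, tauS) {
  out <- numeric(length(s))
  on <- s >= 0
  sp <- s[on]
  if (tauS <= 0) {                       # instantaneous-synapse limit
    out[on] <- exp(-sp / tau2) / tau2
  } else if (abs(tau2 - tauS) < 1e-12 * tau2) {
    out[on] <- sp / tau2^2 * exp(-sp / tau2)
  } else {
    out[on] <- (exp(-sp / tau2) - exp(-sp / tauS)) / (tau2 - tauS)
  }
  out
}

# Sum of psp kernels over pulse onsets; x(t) = D * psp_shape(t).
psp_shape <- function(t, stim, params) {
  out <- numeric(length(t))
  for (tk in pulse_times(stim))
    out <- out + psp_kernel(t - tk, params$tau2, params$tauS)
  out
}

# Drive for the stimulus amplitude under the given parameters.
stim_drive <- function(stim, params, A = stim$A) {
  if (is.na(A)) stop("stimulus amplitude is unset", call. = FALSE)
  peripheral_drive(effective_amplitude(A, stim$PW, params$tau1), params$alpha1)
}

#' Postsynaptic potential trace
#'
#' Exact solution of the leaky-integrator membrane equation
#' `tau2 * dx/dt = -x + Ipsc(t)`, `x(0) = 0`, driven by the synaptic current
#' of [psc()]. The solution is the superposition, over pulses, of the
#' closed-form double-exponential impulse response; no numerical ODE
#' integration is involved.
#'
#' @param stim a [stimulus_train()] with amplitude set.
#' @param params a [lumped_params()].
#' @param config a [model_config()]; sets the trace extent and sampling.
#' @param times optional explicit time grid, ms.
#' @return A data.frame of class `"psp_trace"` with columns `time` (ms) and
#'   `x` (mA/ms).
#' @examples
#' tr <- psp(stimulus_train(NoP = 2, IPI = 20, PW = 0.525, A = 0.22),
#'           lumped_params(), model_config())
#' max(tr$x)
#' @export
psp <- function(stim, params, config = model_config(), times = NULL) {
  stopifnot(inherits(stim, "stimulus_train"), inherits(params, "lumped_params"))
  if (is.null(times)) {
    T_end <- trial_window(stim, params, config)
    times <- sort(unique(c(seq(0, T_end, length.out = 2048L),
                           pulse_times(stim))))
  }
  D <- stim_drive(stim, params)
  out <- data.frame(time = times, x = D * psp_shape(times, stim, params))
  class(out) <- c("psp_trace", "data.frame")
  out
}

#' Instantaneous firing rate of the secondary-neuron population
#'
#' Sigmoidal rate of the non-homogeneous Poisson spike generator:
#' `lambdaL / (1 + exp((alphaL - x)/sigmaL))`, bounded in `(0, lambdaL)` and
#' increasing in the postsynaptic potential `x`. Arguments of the
#' exponential above 700 (deeply subthreshold potentials at steep slopes)
#' return exactly zero to avoid overflow.
#'
#' @param x postsynaptic potential, mA/ms (vectorised).
#' @param params a [lumped_params()].
#' @return Rate in events/ms.
#' @export
firing_rate <- function(x, params) {
  z <- (params$alphaL - x) / params$sigmaL
  out <- numeric(length(x))
  ok <- z <= 700
  out[ok] <- params$lambdaL / (1 + exp(z[ok]))
  out
}

# Composite-Simpson nodes and weights on [a, b] with step <= `step`
# (even number of intervals, at least 2).
simpson_panel <- function(a, b, step) {
  if (b - a <= 0) return(NULL)
  n <- ceiling((b - a) / step)
  if (n %% 2 == 1) n <- n + 1
  n <- max(n, 2L)
  h <- (b - a) / n
  list(t = a + h * (0:n),
       w = h / 3 * c(1, rep_len(c(4, 2), n - 1), 1))
}

# Quadrature grid for the expected-count integral: panels split at every
# pulse onset (integrand kink), with a refined sub-panel over the first
# 10*tauS after each onset where the synaptic rise is steep.
quad_grid <- function(stim, params, config) {
  T_end <- trial_window(stim, params, config)
  coarse <- if (is.na(config$quad_step)) params$tau2 / 200 else config$quad_step
  fine <- min(coarse, max(params$tauS, 1e-6) / 5)
  breaks <- c(pulse_times(stim), T_end)
  ts <- list(); ws <- list()
  for (i in seq_len(length(breaks) - 1L)) {
    a <- breaks[i]; b <- breaks[i + 1L]
    mid <- min(a + 10 * params$tauS, b)
    for (p in list(simpson_panel(a, mid, fine), simpson_panel(mid, b, coarse))) {
      if (!is.null(p)) { ts[[length(ts) + 1L]] <- p$t; ws[[length(ws) + 1L]] <- p$w }
    }
  }
  t <- unlist(ts, use.names = FALSE)
  list(t = t, w = unlist(ws, use.names = FALSE),
       shape = psp_shape(t, stim, params))
}

#' Expected spike count over a trial
#'
#' Integral of the population firing rate over the trial window, i.e. the
#' expected number of spikes of the non-homogeneous Poisson process. The
#' integrand is the firing rate evaluated along the closed-form postsynaptic
#' potential; the quadrature splits at pulse onsets (see [model_config()]).
#'
#' @inheritParams psp
#' @return Expected count (dimensionless scalar).
#' @export
expected_count <- function(stim, params, config = model_config()) {
  g <- quad_grid(stim, params, config)
  D <- stim_drive(stim, params)
  sum(g$w * firing_rate(D * g$shape, params))
}

#' Model-based psychometric function
#'
#' Detection probability of the hazard model: a stimulus is detected iff at
#' least one spike occurs in the trial window, so
#' `Psi = 1 - exp(-expected_count)`.
#'
#' @param stim a [stimulus_train()] with amplitude set, or an amplitude-free
#'   template if `A` is supplied.
#' @param params a [lumped_params()].
#' @param config a [model_config()].
#' @param A optional vector of amplitudes (mA) at which to evaluate the
#'   curve; overrides the amplitude in `stim` and vectorises efficiently
#'   (the quadrature grid is shared across amplitudes).
#' @return Detection probabilities in `[0, 1)`, one per amplitude.
#' @examples
#' psychometric(stimulus_train(NoP = 1, PW = 0.21), lumped_params(),
#'              A = c(0.4, 0.6, 0.8))
#' @export
psychometric <- function(stim, params, config = model_config(), A = NULL) {
  g <- quad_grid(stim, params, config)
  if (is.null(A)) A <- stim$A
  fA <- effective_amplitude(A, stim$PW, params$tau1)
  D <- peripheral_drive(fA, params$alpha1)
  vapply(D, function(d) {
    1 - exp(-sum(g$w * firing_rate(d * g$shape, params)))
  }, numeric(1))
}

#' Numerical detection threshold
#'
#' Solves `Psi(A) = 0.5` for the amplitude `A50` at which the stimulus is
#' detected with probability one half. Since the psychometric function is
#' nondecreasing in amplitude the root is unique; it is bracketed by doubling
#' the upper amplitude from just above the rheobase
#' `alpha1 / (1 - exp(-PW/tau1))` and then solved by Brent's method
#' ([stats::uniroot()]) to within `root_tol`.
#'
#' @param stim a [stimulus_train()]; its amplitude (if any) is ignored.
#' @param params a [lumped_params()].
#' @param config a [model_config()].
#' @return The threshold amplitude `A50` in mA, with attributes `psi`
#'   (the psychometric value at the solution) and `iterations` (root-solver
#'   iteration count).
#' @examples
#' detection_threshold(stimulus_train(NoP = 1, PW = 0.21), lumped_params())
#' @export
detection_threshold <- function(stim, params, config = model_config()) {
  g <- quad_grid(stim, params, config)
  psi_of <- function(A) {
    D <- peripheral_drive(effective_amplitude(A, stim$PW, params$tau1),
                          params$alpha1)
    1 - exp(-sum(g$w * firing_rate(D * g$shape, params)))
  }
  if (psi_of(0) >= 0.5)
    stop("ill-posed threshold: Psi(0) >= 0.5", call. = FALSE)
  lo <- 0
  hi <- params$alpha1 / (1 - exp(-stim$PW / params$tau1)) * 1.01
  while (psi_of(hi) < 0.5) {
    lo <- hi
    hi <- 2 * hi
    if (hi > config$amplitude_bracket_max)
      stop("threshold unreachable: Psi stays below 0.5 up to ",
           config$amplitude_bracket_max, " mA", call. = FALSE)
  }
  # solve well beyond root_tol so the defining equation Psi(A50) = 0.5
  # itself closes to ~10 * quad_tol
  fit <- stats::uniroot(function(A) psi_of(A) - 0.5, lower = lo, upper = hi,
                        tol = min(config$root_tol, config$root_tol^2))
  structure(fit$root, psi = psi_of(fit$root), iterations = fit$iter)
}

#' Reference detection thresholds for a set of stimulus combinations
#'
#' Convenience wrapper computing [detection_threshold()] for each template.
#'
#' @param combos list of amplitude-free [stimulus_train()] templates,
#'   default [standard_combos()].
#' @param params a [lumped_params()].
#' @param config a [model_config()].
#' @return A data.frame with columns `NoP`, `IPI_ms`, `PW_ms`, `A50_mA`,
#'   `psi_at_A50`, `solver_iterations`.
#' @export
threshold_table <- function(combos = standard_combos(),
                            params = lumped_params(),
                            config = model_config()) {
  rows <- lapply(combos, function(st) {
    a <- detection_threshold(st, params, config)
    data.frame(NoP = st$NoP, IPI_ms = st$IPI, PW_ms = st$PW,
               A50_mA = as.numeric(a), psi_at_A50 = attr(a, "psi"),
               solver_iterations = attr(a, "iterations"))
  })
  do.call(rbind, rows)
}
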