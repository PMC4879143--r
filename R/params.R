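#' Lumped model parameters
#'
#' The six lumped parameters of the hazard model plus the synaptic time
#' constant. Units are mA and ms throughout, so rate-like quantities in
#' mA/ms are numerically identical to A/s and `lambdaL` in events/ms is
#' numerically identical to kHz; the published reference values can
#' therefore be used verbatim.
#'
#' The defaults are the reference values: `alpha1 = 0.125` mA (afferent
#' activation threshold), `tau1 = 0.2` ms (afferent time constant),
#' `tau2 = 45` ms (secondary-neuron membrane time constant),
#' `alphaL = 0.00417` mA/ms (central activation threshold),
#' `sigmaL = 8.33e-5` mA/ms (central slope parameter),
#' `lambdaL = 0.01` events/ms (maximal population firing rate), and
#' `tauS = 1.5` ms (synaptic time constant).
#'
#' @param alpha1,tau1,tau2,alphaL,sigmaL,lambdaL,tauS strictly positive
#'   scalars, see above.
#' @return An object of class `"lumped_params"`.
#' @examples
#' lumped_params()                 # reference parameter set
#' lumped_params(lambdaL = 0.05)   # faster maximal population rate
#' @export
lumped_params <- function(alpha1 = 0.125, tau1 = 0.2, tau2 = 45,
                          alphaL = 0.00417, sigmaL = 8.33e-5,
                          lambdaL = 0.01, tauS = 1.5) {
  p <- list(alpha1 = alpha1, tau1 = tau1, tau2 = tau2, alphaL = alphaL,
            sigmaL = sigmaL, lambdaL = lambdaL, tauS = tauS)
  for (nm in names(p)) {
    v <- p[[nm]]
    if (length(v) != 1L || !is.finite(v) || v <= 0)
      stop(sprintf("'%s' must be a single positive number", nm), call. = FALSE)
  }
  structure(lapply(p, as.numeric), class = "lumped_params")
}

#' @export
print.lumped_params <- function(x, ...) {
  cat("Lumped hazard-model parameters (mA, ms):\n")
  cat(sprintf("  alpha1 = %g mA     tau1 = %g ms    tau2 = %g ms\n",
              x$alpha1, x$tau1, x$tau2))
  cat(sprintf("  alphaL = %g mA/ms  sigmaL = %g mA/ms\n", x$alphaL, x$sigmaL))
  cat(sprintf("  lambdaL = %g events/ms  tauS = %g ms\n", x$lambdaL, x$tauS))
  invisible(x)
}

#' Numerical configuration of the forward model
#'
#' Controls the trial window, the quadrature of the expected spike count and
#' the threshold root solve.
#'
#' The trial window `T` runs from stimulus onset to
#' `last pulse time + window_factor * tau2`; with the default factor 15 the
#' postsynaptic potential has decayed by `exp(-15)` at the window end, so the
#' truncated hazard tail is far below `quad_tol`, and the window stays well
#' within the ~3 s inter-stimulus spacing of the experiments.
#'
#' Quadrature is composite Simpson on panels split at every pulse onset
#' (where the integrand has a kink); within a panel the step is
#' `min(quad_step, tau2/200)`, refined to `tauS/5` over the first `10*tauS`
#' after each onset where the synaptic kernel is steep.
#'
#' @param window_factor multiple of `tau2` appended after the last pulse.
#' @param quad_step quadrature step in ms, or `NA` for the
#'   `tau2/200` rule.
#' @param quad_tol target absolute error of the expected spike count.
#' @param root_tol absolute tolerance on the threshold amplitude, mA.
#' @param amplitude_bracket_max largest amplitude (mA) tried while expanding
#'   the root bracket before declaring the threshold unreachable.
#' @return An object of class `"model_config"`.
#' @export
model_config <- function(window_factor = 15, quad_step = NA_real_,
                         quad_tol = 1e-9, root_tol = 1e-6,
                         amplitude_bracket_max = 1000) {
  stopifnot(window_factor > 0, quad_tol > 0, root_tol > 0,
            amplitude_bracket_max > 0,
            is.na(quad_step) || quad_step > 0)
  structure(list(window_factor = as.numeric(window_factor),
                 quad_step = as.numeric(quad_step),
                 quad_tol = as.numeric(quad_tol),
                 root_tol = as.numeric(root_tol),
                 amplitude_bracket_max = as.numeric(amplitude_bracket_max)),
            class = "model_config")
}

# End of the trial window in ms for a stimulus under a configuration.
trial_window <- function(stim, params, config) {
  max(pulse_times(stim)) + config$window_factor * params$tau2
}
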