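#' Limit postsynaptic-potential amplitude per pulse
#'
#' In the instantaneous-synapse limit (`tauS -> 0`) each pulse contributes a
#' decaying exponential `B * exp(-(t - t_k)/tau2)` to the postsynaptic
#' potential, with peak `B = pi * [fA - alpha1]+ / tau2`. The division by
#' `tau2` follows from the impulse response of the leaky integrator (and is
#' required for dimensional consistency with the central threshold, mA/ms).
#'
#' @param fA effective amplitude, mA (vectorised).
#' @param alpha1 afferent activation threshold, mA.
#' @param tau2 secondary-neuron time constant, ms.
#' @return Peak amplitude `B` in mA/ms.
#' @export
limit_psp_amplitude <- function(fA, alpha1, tau2) {
  stopifnot(tau2 > 0)
  peripheral_drive(fA, alpha1) / tau2
}

# Case labels for how a double-pulse limit PSP spends time above alphaL.
.case_labels <- c("SECOND_PULSE_ONLY", "TWO_INTERVALS", "SPANNING_INTERVAL")

#' Supra-threshold geometry of a double-pulse limit PSP
#'
#' For a double pulse in the `tauS -> 0`, `sigmaL -> 0` limit, classifies
#' how the potential `x0(t) = B * (exp(-t/tau2) + exp(-(t-IPI)/tau2) H(t-IPI))`
#' spends time above the central threshold `alphaL`, and evaluates the total
#' supra-threshold duration `DeltaT` in closed form:
#' * `SECOND_PULSE_ONLY` (case 1): each pulse alone stays below threshold,
#'   only their summation crosses — one interval after the second pulse;
#'   `DeltaT1 = tau2 * (log(1 + exp(-IPI/tau2)) - log(alphaL/B))`.
#' * `TWO_INTERVALS` (case 2): each pulse crosses but the potential dips
#'   below threshold between them;
#'   `DeltaT2 = tau2 * (log(1 + exp(-IPI/tau2)) - 2*log(alphaL/B))`.
#' * `SPANNING_INTERVAL` (case 3): the first pulse crosses and the potential
#'   is still above threshold at the second onset — one spanning interval;
#'   `DeltaT3 = IPI + tau2 * (log(1 + exp(-IPI/tau2)) - log(alphaL/B))`.
#'
#' @param B per-pulse peak of the limit PSP, mA/ms.
#' @param alphaL central activation threshold, mA/ms.
#' @param tau2 secondary-neuron time constant, ms.
#' @param IPI interpulse interval, ms.
#' @return A list with `count` (number of supra-threshold intervals, 0, 1 or
#'   2), `case` (label above, or `NA` when the potential never crosses) and
#'   `deltaT` (total supra-threshold time, ms).
#' @examples
#' p <- lumped_params()
#' B <- limit_psp_amplitude(effective_amplitude(0.22, 0.525, p$tau1),
#'                          p$alpha1, p$tau2)
#' supra_threshold_intervals(B, p$alphaL, p$tau2, IPI = 20)
#' @export
supra_threshold_intervals <- function(B, alphaL, tau2, IPI) {
  stopifnot(B >= 0, alphaL > 0, tau2 > 0, IPI > 0)
  decay <- exp(-IPI / tau2)
  if (B * (1 + decay) <= alphaL)
    return(list(count = 0L, case = NA_character_, deltaT = 0))
  lr <- log(alphaL / B)            # log(alphaL/B), negative when B > alphaL
  if (B <= alphaL) {               # case 1: crossing upon the second pulse only
    list(count = 1L, case = .case_labels[1L],
         deltaT = tau2 * (log1p(decay) - lr))
  } else if (B * decay < alphaL) { # case 2: two separate intervals
    list(count = 2L, case = .case_labels[2L],
         deltaT = tau2 * (log1p(decay) - 2 * lr))
  } else {                         # case 3: one spanning interval
    list(count = 1L, case = .case_labels[3L],
         deltaT = IPI + tau2 * (log1p(decay) - lr))
  }
}

#' Interpulse intervals at which the threshold case switches
#'
#' As the interpulse interval decreases, the supra-threshold geometry at the
#' detection threshold switches from case 2 (two intervals) to case 1 or
#' case 3. The switch points are
#' `IPI21 = -tau2 * log(2^(1/(tau2*lambdaL)) - 1)` and
#' `IPI23 = tau2 * log(sqrt(2^(1/(tau2*lambdaL)) + 1/4) - 1/2)`.
#' Exactly one of the two is positive (and hence geometrically realisable)
#' depending on whether `lambdaL*tau2` exceeds 1.
#'
#' @param tau2 secondary-neuron time constant, ms.
#' @param lambdaL maximal population firing rate, events/ms.
#' @return A list with elements `IPI21` and `IPI23` (ms, possibly negative).
#' @examples
#' case_boundaries(45, 0.01)   # IPI23 ~ 24.3 ms, IPI21 < 0
#' @export
case_boundaries <- function(tau2, lambdaL) {
  stopifnot(tau2 > 0, lambdaL > 0)
  g <- 2^(1 / (tau2 * lambdaL))
  if (abs(tau2 * lambdaL - 1) < 1e-12)
    stop("case boundaries are undefined at lambdaL * tau2 == 1", call. = FALSE)
  list(IPI21 = -tau2 * log(g - 1),
       IPI23 = tau2 * log(sqrt(g + 0.25) - 0.5))
}

#' Monotonicity of the threshold-versus-IPI curve
#'
#' Classifies the dependence of the double-pulse detection threshold on the
#' interpulse interval by the product `lambdaL * tau2`: below 1 the curve is
#' non-monotone with an interior minimum at `IPI23`; above 1 it increases
#' monotonically.
#'
#' @inheritParams case_boundaries
#' @return `"NON_MONOTONE"` or `"MONOTONE_INCREASING"`; the degenerate
#'   product of exactly 1 returns `"BOUNDARY"` with a warning.
#' @export
monotonicity_class <- function(tau2, lambdaL) {
  stopifnot(tau2 > 0, lambdaL > 0)
  prod <- lambdaL * tau2
  if (abs(prod - 1) < 1e-12) {
    warning("lambdaL * tau2 is exactly 1: boundary classification")
    return("BOUNDARY")
  }
  if (prod < 1) "NON_MONOTONE" else "MONOTONE_INCREASING"
}

#' Closed-form detection threshold in the limit model
#'
#' In the `tauS -> 0`, `sigmaL -> 0` limit the psychometric function is
#' `Psi = 1 - exp(-lambdaL * DeltaT)`, so the threshold satisfies
#' `lambdaL * DeltaT = log 2`. For a single pulse
#' `DeltaT = tau2 * log(B/alphaL)`, giving `B = alphaL * 2^(1/(lambdaL*tau2))`
#' directly. For a double pulse the equation is inverted for `B` in the case
#' whose validity inequalities hold at the candidate: the case-2 candidate is
#' tried first and, if invalid, case 1 or case 3 is selected by the sign of
#' `lambdaL*tau2 - 1`. The threshold amplitude then follows from
#' `A50 = (B*tau2/pi + alpha1) / (1 - exp(-PW/tau1))`.
#'
#' @param PW pulse width, ms.
#' @param IPI interpulse interval, ms (double pulses only).
#' @param params a [lumped_params()]; only `alpha1`, `tau1`, `tau2`,
#'   `alphaL`, `lambdaL` are used (the limits remove `sigmaL` and `tauS`).
#' @param NoP 1 or 2.
#' @return Threshold `A50` in mA, with attributes `B` (limit PSP peak at
#'   threshold, mA/ms) and, for double pulses, `case` (the supra-threshold
#'   case label at threshold).
#' @examples
#' analytic_threshold(PW = 0.21, params = lumped_params(), NoP = 1)
#' analytic_threshold(PW = 0.525, IPI = 50, params = lumped_params(), NoP = 2)
#' @export
analytic_threshold <- function(PW, IPI = NA_real_, params = lumped_params(),
                               NoP = 2) {
  stopifnot(NoP %in% c(1, 2), PW > 0)
  tau2 <- params$tau2; alphaL <- params$alphaL; lambdaL <- params$lambdaL
  need <- log(2) / (lambdaL * tau2)       # required log(B/alphaL) budget
  if (NoP == 1) {
    B <- alphaL * exp(need)
    case <- NA_character_
  } else {
    if (!is.finite(IPI) || IPI <= 0)
      stop("'IPI' must be positive for double pulses", call. = FALSE)
    decay <- exp(-IPI / tau2)
    # Case 2 candidate: log(B/alphaL) = (need - log(1+decay)) / 2.
    lb2 <- (need - log1p(decay)) / 2
    B2 <- alphaL * exp(lb2)
    if (B2 > alphaL && B2 * decay < alphaL) {
      B <- B2; case <- .case_labels[2L]
    } else if (lambdaL * tau2 > 1) {
      # Short IPI below IPI21: crossing upon the second pulse only.
      B <- alphaL * exp(need - log1p(decay))
      case <- .case_labels[1L]
    } else {
      # Short IPI below IPI23: one spanning interval.
      B <- alphaL * exp(need - IPI / tau2 - log1p(decay))
      case <- .case_labels[3L]
    }
  }
  fA <- B * tau2 / pi + params$alpha1
  A50 <- fA / (1 - exp(-PW / params$tau1))
  structure(A50, B = B, case = case)
}

#' Threshold as a function of the interpulse interval
#'
#' Computes the double-pulse detection threshold over a grid of interpulse
#' intervals, either from the closed-form limit theory
#' ([analytic_threshold()]) or from the full numerical model
#' ([detection_threshold()]).
#'
#' @param IPI_grid vector of positive interpulse intervals, ms.
#' @param PW pulse width, ms.
#' @param params a [lumped_params()].
#' @param mode `"analytic"` or `"numeric"`.
#' @param config a [model_config()] (numeric mode only).
#' @return A data.frame with columns `IPI_ms`, `A50_mA`, `case_label`
#'   (analytic mode; `NA` in numeric mode) and `lambdaL_tau2_product`.
#' @examples
#' threshold_curve(c(10, 25, 50), PW = 0.525, params = lumped_params())
#' @export
threshold_curve <- function(IPI_grid, PW, params = lumped_params(),
                            mode = c("analytic", "numeric"),
                            config = model_config()) {
  mode <- match.arg(mode)
  stopifnot(all(IPI_grid > 0))
  rows <- lapply(IPI_grid, function(ipi) {
    if (mode == "analytic") {
      a <- analytic_threshold(PW = PW, IPI = ipi, params = params, NoP = 2)
      data.frame(IPI_ms = ipi, A50_mA = as.numeric(a),
                 case_label = attr(a, "case"),
                 lambdaL_tau2_product = params$lambdaL * params$tau2)
    } else {
      st <- stimulus_train(NoP = 2, IPI = ipi, PW = PW)
      a <- detection_threshold(st, params, config)
      data.frame(IPI_ms = ipi, A50_mA = as.numeric(a),
                 case_label = NA_character_,
                 lambdaL_tau2_product = params$lambdaL * params$tau2)
    }
  })
  do.call(rbind, rows)
}
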