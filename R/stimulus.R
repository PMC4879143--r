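#' Electrocutaneous stimulus train
#'
#' A square-wave pulse train delivered through an intra-epidermal needle
#' electrode, described by its three temporal properties and its amplitude:
#' the number of pulses `NoP`, the interpulse interval `IPI` (ms), the pulse
#' width `PW` (ms) and the amplitude `A` (mA).
#'
#' @param NoP integer pulse count, `NoP >= 1`.
#' @param PW pulse width in ms, strictly positive (experimentally `< 1` ms so
#'   that a single pulse evokes at most one afferent spike).
#' @param IPI interpulse interval in ms; required (and strictly positive)
#'   when `NoP > 1`, ignored for single pulses.
#' @param A stimulus amplitude in mA, `A >= 0`. May be `NA` for a template
#'   whose amplitude is to be solved for (see [detection_threshold()]).
#'
#' @return An object of class `"stimulus_train"`: a list with elements
#'   `NoP`, `IPI`, `PW`, `A`.
#'
#' @examples
#' stimulus_train(NoP = 2, IPI = 20, PW = 0.525, A = 0.22)
#' @export
stimulus_train <- function(NoP = 1L, PW, IPI = NA_real_, A = NA_real_) {
  NoP <- as.integer(NoP)
  if (length(NoP) != 1L || is.na(NoP) || NoP < 1L)
    stop("'NoP' must be a single integer >= 1", call. = FALSE)
  if (length(PW) != 1L || !is.finite(PW) || PW <= 0)
    stop("'PW' must be a single positive pulse width in ms", call. = FALSE)
  if (NoP > 1L) {
    if (length(IPI) != 1L || !is.finite(IPI) || IPI <= 0)
      stop("'IPI' must be a single positive interval in ms when NoP > 1",
           call. = FALSE)
  } else {
    IPI <- NA_real_
  }
  if (length(A) != 1L || (!is.na(A) && (!is.finite(A) || A < 0)))
    stop("'A' must be a single non-negative amplitude in mA (or NA)",
         call. = FALSE)
  structure(list(NoP = NoP, IPI = as.numeric(IPI), PW = as.numeric(PW),
                 A = as.numeric(A)),
            class = "stimulus_train")
}

#' @export
print.stimulus_train <- function(x, ...) {
  cat(sprintf("Stimulus train: NoP = %d, PW = %g ms%s%s\n", x$NoP, x$PW,
              if (x$NoP > 1L) sprintf(", IPI = %g ms", x$IPI) else "",
              if (is.na(x$A)) ", A = <unset>" else sprintf(", A = %g mA", x$A)))
  invisible(x)
}

#' Replace the amplitude of a stimulus train
#'
#' @param stim a [stimulus_train()].
#' @param A new amplitude in mA.
#' @return The stimulus with amplitude `A`.
#' @export
set_amplitude <- function(stim, A) {
  stopifnot(inherits(stim, "stimulus_train"))
  stimulus_train(NoP = stim$NoP, PW = stim$PW, IPI = stim$IPI, A = A)
}

# Pulse onset times in ms: 0, IPI, ..., (NoP-1)*IPI.
pulse_times <- function(stim) {
  if (stim$NoP == 1L) 0 else (seq_len(stim$NoP) - 1) * stim$IPI
}

#' Standard stimulus combinations
#'
#' The four combinations of temporal properties used throughout the
#' psychophysical study this model targets: single pulses of 0.21 and
#' 0.525 ms width, and 0.525-ms double pulses at interpulse intervals of
#' 20 and 50 ms. Optionally the fifth combination (IPI = 30 ms) used to
#' expose the shallow non-monotone effect of the central slope parameter.
#'
#' @param include_ipi30 also include `(NoP = 2, IPI = 30, PW = 0.525)`.
#' @return A list of amplitude-free [stimulus_train()] templates.
#' @export
standard_combos <- function(include_ipi30 = FALSE) {
  combos <- list(
    stimulus_train(NoP = 1, PW = 0.21),
    stimulus_train(NoP = 1, PW = 0.525),
    stimulus_train(NoP = 2, IPI = 20, PW = 0.525),
    stimulus_train(NoP = 2, IPI = 50, PW = 0.525)
  )
  if (include_ipi30)
    combos <- c(combos, list(stimulus_train(NoP = 2, IPI = 30, PW = 0.525)))
  combos
}

# Short label like "NoP=2, IPI=20, PW=0.525" for tables and messages.
combo_label <- function(stim) {
  if (stim$NoP == 1L)
    sprintf("NoP=1, PW=%g", stim$PW)
  else
    sprintf("NoP=%d, IPI=%g, PW=%g", stim$NoP, stim$IPI, stim$PW)
}
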