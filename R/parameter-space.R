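#' Multiplicative ratios of the physical quantities
#'
#' The lumped model parameters absorb fifteen physical quantities (skin and
#' membrane conductivities, nerve-ending density and depth, synaptic gain,
#' secondary-neuron membrane properties, ...). Absolute baselines for these
#' quantities are not identifiable from detection data — only their
#' multiplicative deviations from baseline matter — so perturbations are
#' represented as dimensionless ratios with baseline 1.
#'
#' Quantities: `Vth` (afferent firing threshold), `c0` (superficial tissue
#' conductivity), `c1` (nerve-ending resistance per length), `C1`/`G1`
#' (nerve-ending membrane capacitance/conductance), `rho` (nerve-ending
#' surface density), `h` (nerve-ending depth), `C2`/`G2` (secondary-neuron
#' membrane capacitance/conductance), `alphah`/`sigmah` (secondary-neuron
#' activation threshold/slope), `l` (number of secondary neurons),
#' `lambdah` (maximal single-neuron firing rate), `gbar` (maximal AMPA
#' synaptic conductance), `K` (synaptic potential gradient).
#'
#' @param ... named ratios to override (all default 1, must be positive).
#' @return An object of class `"physical_ratios"`: a named numeric vector.
#' @examples
#' physical_ratios(rho = 0.172, h = 1.3, Vth = 0.45)
#' @export
physical_ratios <- function(...) {
  r <- c(Vth = 1, c0 = 1, c1 = 1, C1 = 1, G1 = 1, rho = 1, h = 1,
         C2 = 1, G2 = 1, alphah = 1, sigmah = 1, l = 1, lambdah = 1,
         gbar = 1, K = 1)
  over <- c(...)
  if (length(over)) {
    bad <- setdiff(names(over), names(r))
    if (length(bad))
      stop("unknown physical quantities: ", paste(bad, collapse = ", "),
           call. = FALSE)
    if (any(over <= 0))
      stop("all ratios must be strictly positive", call. = FALSE)
    r[names(over)] <- over
  }
  structure(r, class = "physical_ratios")
}

#' Lumped-parameter multipliers implied by physical ratios
#'
#' Propagates multiplicative perturbations of the physical quantities to the
#' six lumped parameters through their defining expressions:
#' `alpha1` scales with `c0*c1*G1*Vth*h^2`; `tau1` with `C1/G1`; `tau2` with
#' `C2/G2`; `alphaL` with `c0*c1*G1*G2*Vth*alphah/(rho*gbar*K)`; `sigmaL`
#' identically but with `sigmah` in place of `alphah`; and `lambdaL` with
#' `l*lambdah`. Ratio combinations inside the redundancy subgroups
#' (`{Vth, c0, c1}`, `{rho, gbar, K}`, `{l, lambdah}`) that multiply to 1
#' leave every lumped parameter unchanged.
#'
#' @param r a [physical_ratios()].
#' @return Named numeric vector of multipliers `alpha1`, `tau1`, `tau2`,
#'   `alphaL`, `sigmaL`, `lambdaL`.
#' @examples
#' lumped_multipliers(physical_ratios(Vth = 0.45, h = 1.3))
#' @export
lumped_multipliers <- function(r) {
  stopifnot(inherits(r, "physical_ratios"))
  r <- unclass(r)
  peri <- r[["c0"]] * r[["c1"]] * r[["G1"]] * r[["Vth"]]
  central <- peri * r[["G2"]] / (r[["rho"]] * r[["gbar"]] * r[["K"]])
  c(alpha1 = peri * r[["h"]]^2,
    tau1 = r[["C1"]] / r[["G1"]],
    tau2 = r[["C2"]] / r[["G2"]],
    alphaL = central * r[["alphah"]],
    sigmaL = central * r[["sigmah"]],
    lambdaL = r[["l"]] * r[["lambdah"]])
}

#' Apply lumped multipliers to a baseline parameter set
#'
#' @param baseline a [lumped_params()].
#' @param m named multipliers as returned by [lumped_multipliers()] (any
#'   subset of `alpha1, tau1, tau2, alphaL, sigmaL, lambdaL`).
#' @return A new [lumped_params()]; `tauS` is never scaled.
#' @export
apply_multipliers <- function(baseline, m) {
  stopifnot(inherits(baseline, "lumped_params"), all(m > 0))
  p <- unclass(baseline)
  bad <- setdiff(names(m), c("alpha1", "tau1", "tau2", "alphaL", "sigmaL",
                             "lambdaL"))
  if (length(bad))
    stop("unknown lumped parameters: ", paste(bad, collapse = ", "),
         call. = FALSE)
  for (nm in names(m)) p[[nm]] <- p[[nm]] * m[[nm]]
  do.call(lumped_params, p)
}

#' Parameters derived from a full set of physical ratios
#'
#' @param baseline a [lumped_params()].
#' @param r a [physical_ratios()].
#' @return The perturbed [lumped_params()].
#' @export
perturbed_params <- function(baseline, r) {
  apply_multipliers(baseline, lumped_multipliers(r))
}

# The ten physical quantities that span all lumped parameters (redundant
# partners c0, c1, K and l excluded), and the six lumped names.
.sweepable_physical <- c("Vth", "C1", "G1", "rho", "h", "C2", "G2",
                         "alphah", "sigmah", "lambdah")
.lumped_names <- c("alpha1", "tau1", "tau2", "alphaL", "sigmaL", "lambdaL")

#' Single-parameter threshold sweep
#'
#' Varies one physical quantity or one lumped parameter over a grid of
#' multiplicative factors (all other parameters at baseline) and recomputes
#' the detection threshold for each stimulus combination at each factor.
#'
#' @param parameter name of a physical quantity (see [physical_ratios()]) or
#'   lumped parameter.
#' @param factors grid of positive factors, default 45 points on
#'   `[0.60, 1.70]` (steps of 0.025).
#' @param combos stimulus templates; defaults to the four standard
#'   combinations, plus the IPI = 30 ms combination when sweeping the slope
#'   parameters `sigmah`/`sigmaL` whose non-monotone effect is visible there.
#' @param baseline a [lumped_params()].
#' @param config a [model_config()].
#' @return A data.frame with columns `parameter`, `factor`, `NoP`, `IPI_ms`,
#'   `PW_ms`, `A50_mA` (`NA` with `unreachable = TRUE` where the bracket
#'   expansion fails).
#' @examples
#' sweep_thresholds("h", factors = c(0.8, 1, 1.2),
#'                  combos = standard_combos()[3])
#' @export
sweep_thresholds <- function(parameter, factors = seq(0.60, 1.70, by = 0.025),
                             combos = NULL, baseline = lumped_params(),
                             config = model_config()) {
  stopifnot(all(factors > 0), !is.unsorted(factors))
  is_lumped <- parameter %in% .lumped_names
  if (!is_lumped && !(parameter %in% names(physical_ratios())))
    stop("unknown parameter: ", parameter, call. = FALSE)
  if (is.null(combos))
    combos <- standard_combos(include_ipi30 =
                                parameter %in% c("sigmah", "sigmaL"))
  rows <- list()
  for (f in factors) {
    if (is_lumped) {
      m <- stats::setNames(f, parameter)
    } else {
      r <- do.call(physical_ratios, stats::setNames(list(f), parameter))
      m <- lumped_multipliers(r)
    }
    p <- apply_multipliers(baseline, m)
    for (st in combos) {
      a50 <- tryCatch(as.numeric(detection_threshold(st, p, config)),
                      error = function(e) NA_real_)
      rows[[length(rows) + 1L]] <-
        data.frame(parameter = parameter, factor = f, NoP = st$NoP,
                   IPI_ms = st$IPI, PW_ms = st$PW, A50_mA = a50,
                   unreachable = is.na(a50))
    }
  }
  do.call(rbind, rows)
}

#' Classify the monotonicity of a sweep curve
#'
#' Labels each `(parameter, combination)` curve of a sweep result as
#' `MONOTONE_UP`, `MONOTONE_DOWN`, `NON_MONOTONE`, or `FLAT`, by the signs
#' of successive differences exceeding a noise tolerance (default ten times
#' the root tolerance, so solver jitter is not mistaken for an extremum).
#'
#' @param result data.frame from [sweep_thresholds()] (at least 5 grid
#'   points per curve).
#' @param tol absolute noise tolerance in mA.
#' @return A data.frame with one row per curve: `parameter`, `NoP`,
#'   `IPI_ms`, `PW_ms`, `monotonicity_label`.
#' @export
classify_monotonicity <- function(result, tol = 10 * model_config()$root_tol) {
  key <- paste(result$parameter, result$NoP, result$IPI_ms, result$PW_ms)
  rows <- lapply(split(result, key), function(d) {
    d <- d[order(d$factor), ]
    if (sum(!is.na(d$A50_mA)) < 5)
      stop("need at least 5 grid points per curve", call. = FALSE)
    dif <- diff(d$A50_mA[!is.na(d$A50_mA)])
    sgn <- sign(dif[abs(dif) > tol])
    label <- if (length(sgn) == 0) "FLAT"
             else if (all(sgn > 0)) "MONOTONE_UP"
             else if (all(sgn < 0)) "MONOTONE_DOWN"
             else "NON_MONOTONE"
    data.frame(parameter = d$parameter[1], NoP = d$NoP[1],
               IPI_ms = d$IPI_ms[1], PW_ms = d$PW_ms[1],
               monotonicity_label = label)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
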