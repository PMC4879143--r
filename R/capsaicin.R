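#' Linear fiber-density timeline
#'
#' After high-dose topical capsaicin, intra-epidermal nerve fibers
#' degenerate and then regrow at an approximately constant rate. Given the
#' measured density ratios at two anchor days (Day 7 and Day 84 in the
#' literature), the ratios on other post-treatment days are obtained by
#' linear inter-/extrapolation through the anchors. Day 0 is the untreated
#' baseline and is fixed at ratio 1 (it does not lie on the regrowth line).
#'
#' @param days days at which to evaluate the timeline.
#' @param anchor7,anchor84 density ratios at days 7 and 84, in `(0, 1]`.
#' @return Numeric vector of density ratios `r_rho`, one per day.
#' @examples
#' density_timeline(c(0, 2, 7, 28, 84))
#' @export
density_timeline <- function(days, anchor7 = 0.21, anchor84 = 0.80) {
  stopifnot(all(days >= 0), anchor7 > 0, anchor7 <= 1,
            anchor84 > 0, anchor84 <= 1)
  slope <- (anchor84 - anchor7) / (84 - 7)
  r <- anchor7 + slope * (days - 7)
  r[days == 0] <- 1
  r
}

# Per-day perturbation ratios of the five physical quantities affected by
# the capsaicin scenario.  rho: fiber density (degeneration + regrowth);
# h: nerve-ending depth (retraction); Vth: peripheral firing threshold
# (neurogenic inflammation, resolved after ~3 days); G2, gbar: dorsal-horn
# membrane conductance and AMPA synaptic gain (central sensitization).
.capsaicin_table <- data.frame(
  day  = c(0, 2, 7, 28, 84),
  rho  = c(1, 0.172, 0.21, 0.371, 0.80),
  h    = c(1, 1.3, 1.25, 1.23, 1.15),
  Vth  = c(1, 0.45, 1, 1, 1),
  G2   = c(1, 0.92, 0.9, 0.96, 0.98),
  gbar = c(1, 1.832, 4.608, 3.234, 1.4)
)

.study_variants <- c("FULL", "NO_FUNCTIONAL", "NO_CENTRAL", "NO_PERIPHERAL")

#' Study-day perturbation scenarios
#'
#' The built-in five-day capsaicin scenario: per study day, the
#' multiplicative ratios of the five physical quantities perturbed by the
#' treatment (`rho`, `h`, `Vth`, `G2`, `gbar`). The `rho` row is consistent
#' with [density_timeline()] (Day 2 and Day 28 from the Day 7/84 anchors,
#' rounded to 3 decimals).
#'
#' @return A data.frame with columns `day`, `rho`, `h`, `Vth`, `G2`, `gbar`.
#' @export
scenario_table <- function() .capsaicin_table

#' Ratios of an ablation variant
#'
#' The ablation variants switch off the functional (excitability/synaptic)
#' components of the scenario while always keeping the structural
#' degeneration (`rho`, `h`):
#' * `FULL`: all five ratios as given.
#' * `NO_FUNCTIONAL`: only degeneration; `Vth`, `G2`, `gbar` reset to 1.
#' * `NO_CENTRAL`: central plasticity omitted; `G2`, `gbar` reset to 1.
#' * `NO_PERIPHERAL`: peripheral sensitization omitted; `Vth` reset to 1.
#'
#' @param full a [physical_ratios()] holding the FULL-scenario ratios.
#' @param variant one of `"FULL"`, `"NO_FUNCTIONAL"`, `"NO_CENTRAL"`,
#'   `"NO_PERIPHERAL"`.
#' @return The variant's [physical_ratios()].
#' @export
variant_ratios <- function(full, variant = .study_variants) {
  stopifnot(inherits(full, "physical_ratios"))
  variant <- match.arg(variant)
  reset <- switch(variant,
                  FULL = character(0),
                  NO_FUNCTIONAL = c("Vth", "G2", "gbar"),
                  NO_CENTRAL = c("G2", "gbar"),
                  NO_PERIPHERAL = "Vth")
  full[reset] <- 1
  full
}

# physical_ratios for one study day of the built-in scenario.
day_ratios <- function(day) {
  row <- .capsaicin_table[.capsaicin_table$day == day, ]
  if (nrow(row) != 1L)
    stop("no scenario for day ", day, "; available: ",
         paste(.capsaicin_table$day, collapse = ", "), call. = FALSE)
  physical_ratios(rho = row$rho, h = row$h, Vth = row$Vth, G2 = row$G2,
                  gbar = row$gbar)
}

#' Run the five-day capsaicin study
#'
#' Computes the detection threshold for every study day, ablation variant
#' and stimulus combination: the day's ratios (restricted by the variant)
#' are mapped to lumped-parameter multipliers, applied to the baseline, and
#' the threshold is solved numerically.
#'
#' @param variants subset of `"FULL"`, `"NO_FUNCTIONAL"`, `"NO_CENTRAL"`,
#'   `"NO_PERIPHERAL"`.
#' @param combos stimulus templates, default the four standard combinations.
#' @param baseline a [lumped_params()].
#' @param config a [model_config()].
#' @param days study days, default `c(0, 2, 7, 28, 84)`.
#' @return A data.frame with columns `day`, `variant`, `NoP`, `IPI_ms`,
#'   `PW_ms`, `A50_mA`, `pct_change_vs_day0`.
#' @examples
#' \donttest{
#' run_study(variants = "FULL", combos = standard_combos()[c(1, 3)])
#' }
#' @export
run_study <- function(variants = .study_variants, combos = standard_combos(),
                      baseline = lumped_params(), config = model_config(),
                      days = .capsaicin_table$day) {
  variants <- match.arg(variants, .study_variants, several.ok = TRUE)
  rows <- list()
  for (day in days) {
    full <- day_ratios(day)
    for (v in variants) {
      p <- perturbed_params(baseline, variant_ratios(full, v))
      for (st in combos) {
        a50 <- as.numeric(detection_threshold(st, p, config))
        rows[[length(rows) + 1L]] <-
          data.frame(day = day, variant = v, NoP = st$NoP, IPI_ms = st$IPI,
                     PW_ms = st$PW, A50_mA = a50)
      }
    }
  }
  out <- do.call(rbind, rows)
  base <- out[out$day == 0 & out$variant == out$variant[1], ]
  key <- function(d) paste(d$NoP, d$IPI_ms, d$PW_ms)
  base_map <- stats::setNames(base$A50_mA, key(base))
  out$pct_change_vs_day0 <- 100 * (out$A50_mA / base_map[key(out)] - 1)
  rownames(out) <- NULL
  out
}

#' Psychometric curves across study days
#'
#' Detection-probability curves under the FULL scenario of each requested
#' study day, for one stimulus combination over an amplitude grid.
#'
#' @param combo an amplitude-free [stimulus_train()] template.
#' @param amplitudes amplitude grid, mA.
#' @param days study days, default all five.
#' @param baseline a [lumped_params()].
#' @param config a [model_config()].
#' @return A data.frame with columns `day`, `NoP`, `IPI_ms`, `PW_ms`,
#'   `A_mA`, `psi`.
#' @export
psychometric_curves <- function(combo, amplitudes,
                                days = .capsaicin_table$day,
                                baseline = lumped_params(),
                                config = model_config()) {
  stopifnot(all(amplitudes >= 0))
  rows <- lapply(days, function(day) {
    p <- perturbed_params(baseline, day_ratios(day))
    data.frame(day = day, NoP = combo$NoP, IPI_ms = combo$IPI,
               PW_ms = combo$PW, A_mA = amplitudes,
               psi = psychometric(combo, p, config, A = amplitudes))
  })
  do.call(rbind, rows)
}

#' Check the qualitative capsaicin threshold patterns
#'
#' Asserts the qualitative pattern of threshold changes against the Day-0
#' baseline (tolerance `tol`, default 2% of baseline): single-pulse
#' thresholds rise on Days 2 and 7; double-pulse thresholds rise on Days 7,
#' 28 and 84; the Day-2 change for the 20-ms double pulse is within
#' tolerance of zero (the headline dissociation between single- and
#' double-pulse stimuli); and on Days 2-28 every ablation variant's
#' threshold is at least the FULL variant's (functional plasticity
#' compensates degeneration, so removing it can only raise thresholds).
#'
#' @param result data.frame from [run_study()]; must contain the FULL
#'   variant (the ablation check is skipped for absent variants).
#' @param tol relative tolerance, default 0.02.
#' @return A list with `pass` (logical) and `failures` (character vector
#'   describing each violated assertion).
#' @export
pattern_check <- function(result, tol = 0.02) {
  stopifnot(is.data.frame(result), "FULL" %in% result$variant)
  failures <- character(0)
  note <- function(...) failures <<- c(failures, sprintf(...))
  full <- result[result$variant == "FULL", ]
  key <- function(d) paste(d$NoP, d$IPI_ms, d$PW_ms)
  base <- full[full$day == 0, ]
  base_map <- stats::setNames(base$A50_mA, key(base))
  for (i in seq_len(nrow(full))) {
    row <- full[i, ]
    b <- base_map[key(row)]
    rel <- row$A50_mA / b - 1
    if (row$NoP == 1 && row$day %in% c(2, 7) && rel <= tol)
      note("single-pulse threshold not raised on day %d (%s): %+.1f%%",
           row$day, combo_label(row_to_stim(row)), 100 * rel)
    if (row$NoP == 2 && row$day %in% c(7, 28, 84) && rel <= tol)
      note("double-pulse threshold not raised on day %d (%s): %+.1f%%",
           row$day, combo_label(row_to_stim(row)), 100 * rel)
    if (row$NoP == 2 && row$day == 2 && isTRUE(row$IPI_ms == 20) &&
        abs(rel) > tol)
      note("day-2 double-pulse (IPI=20) change exceeds tolerance: %+.1f%%",
           100 * rel)
  }
  full_map <- stats::setNames(full$A50_mA, paste(full$day, key(full)))
  abl <- result[result$variant != "FULL" & result$day %in% c(2, 7, 28), ]
  for (i in seq_len(nrow(abl))) {
    row <- abl[i, ]
    f <- full_map[paste(row$day, key(row))]
    if (is.finite(f) && row$A50_mA < f * (1 - tol))
      note("%s below FULL on day %d (%s): %.3f < %.3f mA", row$variant,
           row$day, combo_label(row_to_stim(row)), row$A50_mA, f)
  }
  list(pass = length(failures) == 0L, failures = failures)
}

# Rebuild a stimulus template from a result row (labels only).
row_to_stim <- function(row) {
  stimulus_train(NoP = row$NoP, PW = row$PW_ms,
                 IPI = if (row$NoP > 1) row$IPI_ms else NA_real_)
}
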