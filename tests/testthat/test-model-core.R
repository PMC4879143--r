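# Independent ODE oracle for the membrane equation tau2*x' = -x + Ipsc(t),
# integrated piecewise between pulse onsets (where the forcing is smooth)
# with a stiff solver.
psp_ode_oracle <- function(stim, params, times) {
  skip_if_not_installed("deSolve")
  D <- nocithresh:::stim_drive(stim, params)
  onsets <- nocithresh:::pulse_times(stim)
  rhs <- function(t, y, parms) {
    Ip <- sum((D / params$tauS) * exp(-(t - onsets[onsets <= t]) / params$tauS))
    list((Ip - y) / params$tau2)
  }
  breaks <- sort(unique(c(onsets, max(times))))
  x0 <- 0
  out_t <- numeric(0); out_x <- numeric(0)
  for (i in seq_len(length(breaks))) {
    a <- breaks[i]; b <- if (i < length(breaks)) breaks[i + 1] else max(times)
    if (b <= a) next
    seg <- sort(unique(c(a, times[times > a & times <= b], b)))
    sol <- deSolve::lsoda(c(x = x0), seg, rhs, NULL,
                          rtol = 1e-11, atol = 1e-13)
    keep <- seg %in% times
    out_t <- c(out_t, seg[keep]); out_x <- c(out_x, sol[keep, "x"])
    x0 <- unname(sol[nrow(sol), "x"])
  }
  unname(out_x[match(times, out_t)])
}

test_that("effective amplitude follows the membrane charging factor", {
  expect_equal(effective_amplitude(0, 0.21, 0.2), 0)
  expect_equal(effective_amplitude(0.22, 0.525, 0.2),
               0.22 * (1 - exp(-2.625)), tolerance = 1e-12)
  expect_equal(effective_amplitude(0.22, 0.525, 0.2), 0.204064,
               tolerance = 1e-5)
  expect_equal(effective_amplitude(1, 1e6, 0.2), 1)  # saturation limit
  expect_lt(effective_amplitude(1, 0.5, 0.2), 1)
  expect_error(effective_amplitude(1, 0, 0.2), "PW")
  expect_error(effective_amplitude(1, 0.5, -1), "tau1")
})

test_that("peripheral drive is threshold-linear with the geometric factor", {
  expect_equal(peripheral_drive(0.125, 0.125), 0)
  expect_equal(peripheral_drive(0.1, 0.125), 0)
  expect_equal(peripheral_drive(0.204064, 0.125), pi * 0.079064,
               tolerance = 1e-12)
  expect_equal(peripheral_drive(0.204064, 0.125), 0.248386, tolerance = 1e-5)
})

test_that("postsynaptic current superposes gated exponential kernels", {
  D <- 0.248386
  expect_equal(psc(0, stim_1_0525, D, 1.5), D / 1.5, tolerance = 1e-12)
  expect_equal(psc(-0.5, stim_1_0525, D, 1.5), 0)
  # superposition at the second onset: fresh kernel plus decayed first pulse
  expect_equal(psc(20, stim_2_20, D, 1.5),
               D / 1.5 + (D / 1.5) * exp(-20 / 1.5), tolerance = 1e-12)
  # decay between pulses
  expect_equal(psc(10, stim_2_20, D, 1.5), (D / 1.5) * exp(-10 / 1.5),
               tolerance = 1e-12)
})

test_that("zero amplitude produces an identically zero trace", {
  tr <- psp(set_amplitude(stim_2_20, 0), ref_params, ref_config)
  expect_true(all(tr$x == 0))
})

test_that("the instantaneous-synapse peak equals the limit amplitude", {
  p0 <- lumped_params(tauS = 1e-9)
  st <- set_amplitude(stim_1_0525, 0.22)
  # sample just after onset, where the vanishing synaptic kernel has peaked
  tr <- psp(st, p0, ref_config, times = c(0, 1e-6, 0.1, 1, 10))
  B <- limit_psp_amplitude(effective_amplitude(0.22, 0.525, p0$tau1),
                           p0$alpha1, p0$tau2)
  expect_equal(B, 0.0055197, tolerance = 1e-4)
  expect_equal(max(tr$x), B, tolerance = 1e-6)
})

test_that("closed-form PSP matches stiff ODE integration on random draws", {
  set.seed(101)
  n_draw <- 100
  for (i in seq_len(n_draw)) {
    f <- stats::runif(4, 0.5, 2)   # scale tau1, tau2, tauS, amplitude
    p <- lumped_params(tau1 = 0.2 * f[1], tau2 = 45 * f[2], tauS = 1.5 * f[3])
    nop <- sample(1:3, 1)
    st <- stimulus_train(NoP = nop, IPI = if (nop > 1) runif(1, 5, 60),
                         PW = runif(1, 0.1, 0.9), A = 0.3 * f[4])
    times <- sort(runif(12, 0, 3 * p$tau2))
    got <- psp(st, p, ref_config, times = times)$x
    want <- psp_ode_oracle(st, p, times)
    expect_equal(got, want, tolerance = 1e-8)
  }
})

test_that("degenerate tau2 == tauS uses the limiting kernel continuously", {
  p_eq <- lumped_params(tau2 = 1.5, tauS = 1.5)
  p_near <- lumped_params(tau2 = 1.5, tauS = 1.5 * (1 + 1e-9))
  st <- set_amplitude(stim_1_0525, 0.22)
  times <- seq(0, 10, by = 0.25)
  expect_equal(psp(st, p_eq, ref_config, times = times)$x,
               psp(st, p_near, ref_config, times = times)$x,
               tolerance = 1e-6)
})

test_that("firing rate is a bounded increasing sigmoid with overflow guard", {
  p <- ref_params
  expect_equal(firing_rate(p$alphaL, p), p$lambdaL / 2)
  expect_equal(firing_rate(1, p), p$lambdaL, tolerance = 1e-12)
  expect_equal(firing_rate(0, p), 0, tolerance = 1e-20)
  x <- seq(0, 0.01, length.out = 50)
  expect_true(all(diff(firing_rate(x, p)) >= 0))
  steep <- lumped_params(sigmaL = 1e-9)
  expect_identical(firing_rate(0, steep), 0)   # guard returns exact zero
})

test_that("expected count vanishes at zero amplitude and ignores the window tail", {
  lam0 <- expected_count(set_amplitude(stim_1_021, 0), ref_params, ref_config)
  expect_lt(lam0, 1e-20)
  st <- set_amplitude(stim_2_20, 0.3)
  lam1 <- expected_count(st, ref_params, ref_config)
  lam2 <- expected_count(st, ref_params, model_config(window_factor = 30))
  expect_equal(lam1, lam2, tolerance = ref_config$quad_tol)
})

test_that("expected count at the closed-form threshold approaches log 2 in the limit", {
  p <- lumped_params(sigmaL = 8.33e-7, tauS = 0.015)
  a50 <- as.numeric(analytic_threshold(PW = 0.525, IPI = 50,
                                       params = ref_params, NoP = 2))
  expect_equal(a50, 0.255401, tolerance = 1e-4)
  lamT <- expected_count(set_amplitude(stim_2_50, a50), p, limit_config)
  expect_equal(lamT, log(2), tolerance = 5e-4)
})

test_that("the psychometric function is a probability, nondecreasing in amplitude", {
  A <- seq(0, 1.2, length.out = 40)
  psi <- psychometric(stim_2_20, ref_params, ref_config, A = A)
  expect_true(all(psi >= 0 & psi < 1))
  expect_true(all(diff(psi) >= 0))
  expect_lt(psychometric(stim_1_021, ref_params, ref_config, A = 0), 1e-10)
})

test_that("numeric thresholds solve Psi = 0.5 and track the closed form", {
  for (st in list(stim_1_021, stim_2_20, stim_2_50)) {
    a <- detection_threshold(st, ref_params, ref_config)
    expect_equal(attr(a, "psi"), 0.5, tolerance = 10 * ref_config$quad_tol)
    ana <- analytic_threshold(PW = st$PW, IPI = st$IPI, params = ref_params,
                              NoP = st$NoP)
    expect_equal(as.numeric(a), as.numeric(ana), tolerance = 0.02)
  }
})

test_that("numeric thresholds converge to the closed form in the limit", {
  p <- lumped_params(sigmaL = 8.33e-7, tauS = 0.015)
  for (st in list(stim_1_021, stim_2_50)) {
    num <- as.numeric(detection_threshold(st, p, limit_config))
    ana <- as.numeric(analytic_threshold(PW = st$PW, IPI = st$IPI,
                                         params = ref_params, NoP = st$NoP))
    expect_equal(num, ana, tolerance = 1e-3)
  }
})

test_that("raising the afferent threshold raises the detection threshold", {
  a_ref <- as.numeric(detection_threshold(stim_2_20, ref_params, ref_config))
  p2 <- lumped_params(alpha1 = 2 * ref_params$alpha1)
  a_hi <- as.numeric(detection_threshold(stim_2_20, p2, ref_config))
  expect_gt(a_hi, a_ref)
})

test_that("threshold solve reports unreachable and ill-posed cases", {
  cfg_small <- model_config(amplitude_bracket_max = 0.05)
  expect_error(detection_threshold(stim_1_021, ref_params, cfg_small),
               "unreachable")
  p_bad <- lumped_params(alphaL = 1e-6, sigmaL = 1e-2, lambdaL = 1)
  expect_error(detection_threshold(stim_1_021, p_bad, ref_config),
               "ill-posed")
})

test_that("threshold_table returns the reference-combination summary", {
  tab <- threshold_table(standard_combos()[c(1, 3)], ref_params, ref_config)
  expect_equal(nrow(tab), 2L)
  expect_named(tab, c("NoP", "IPI_ms", "PW_ms", "A50_mA", "psi_at_A50",
                      "solver_iterations"))
  expect_true(all(abs(tab$psi_at_A50 - 0.5) < 1e-8))
})
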