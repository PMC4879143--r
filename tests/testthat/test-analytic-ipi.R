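# Brute-force oracle: count supra-threshold intervals and total time of the
# limit PSP x0(t) = B * sum_k exp(-(t - k*IPI)/tau2) H(t - k*IPI) on a dense
# time grid.
brute_force_intervals <- function(B, alphaL, tau2, IPI, dt = 0.005) {
  t <- seq(0, IPI + 20 * tau2, by = dt)
  x <- B * (exp(-t / tau2) +
              ifelse(t >= IPI, exp(-(t - IPI) / tau2), 0))
  above <- x > alphaL
  r <- rle(above)
  list(count = sum(r$values), deltaT = dt * sum(above))
}

worked_B <- function(A) {
  limit_psp_amplitude(effective_amplitude(A, 0.525, ref_params$tau1),
                      ref_params$alpha1, ref_params$tau2)
}

test_that("limit PSP amplitude divides the drive by the membrane time constant", {
  expect_equal(limit_psp_amplitude(0.125, 0.125, 45), 0)
  expect_equal(limit_psp_amplitude(0.204064, 0.125, 45), pi * 0.079064 / 45,
               tolerance = 1e-12)
  expect_equal(worked_B(0.22), 0.0055197, tolerance = 1e-4)
  expect_equal(worked_B(0.26), 0.0081098, tolerance = 1e-4)
})

test_that("the three worked amplitudes realise the three crossing geometries", {
  cases <- lapply(c(0.19, 0.22, 0.26), function(A)
    supra_threshold_intervals(worked_B(A), ref_params$alphaL,
                              ref_params$tau2, IPI = 20))
  expect_equal(vapply(cases, `[[`, 1L, "count"), c(1L, 2L, 1L))
  expect_equal(vapply(cases, `[[`, "", "case"),
               c("SECOND_PULSE_ONLY", "TWO_INTERVALS", "SPANNING_INTERVAL"))
  # far subthreshold: no crossing at all
  none <- supra_threshold_intervals(worked_B(0.16), ref_params$alphaL,
                                    ref_params$tau2, IPI = 20)
  expect_equal(none$count, 0L)
  expect_equal(none$deltaT, 0)
})

test_that("closed-form interval counts and durations match brute force", {
  set.seed(202)
  for (i in 1:400) {
    B <- ref_params$alphaL * exp(runif(1, -0.7, 1.5))
    IPI <- runif(1, 2, 120)
    got <- supra_threshold_intervals(B, ref_params$alphaL, ref_params$tau2, IPI)
    want <- brute_force_intervals(B, ref_params$alphaL, ref_params$tau2, IPI)
    expect_equal(got$count, want$count)
    expect_equal(got$deltaT, want$deltaT, tolerance = 0.03)
  }
})

test_that("case boundaries evaluate as derived and flag the critical product", {
  b <- case_boundaries(45, 0.01)
  expect_equal(b$IPI23, 24.332, tolerance = 1e-4)
  expect_lt(b$IPI21, 0)
  b5 <- case_boundaries(45, 0.05)
  expect_equal(b5$IPI21, 45.876, tolerance = 1e-4)
  expect_lt(b5$IPI23, 0)
  expect_error(case_boundaries(100, 0.01), "lambdaL")
  # boundaries collapse to 0 as the product approaches 1
  expect_equal(case_boundaries(45, (1 - 1e-7) / 45)$IPI23, 0, tolerance = 1e-4)
  expect_equal(case_boundaries(45, (1 + 1e-7) / 45)$IPI23, 0, tolerance = 1e-4)
})

test_that("the product lambdaL*tau2 classifies IPI monotonicity", {
  expect_equal(monotonicity_class(45, 0.01), "NON_MONOTONE")
  expect_equal(monotonicity_class(45, 0.05), "MONOTONE_INCREASING")
  expect_warning(cls <- monotonicity_class(100, 0.01), "boundary")
  expect_equal(cls, "BOUNDARY")
})

test_that("analytic thresholds reproduce the derived reference values", {
  a1 <- analytic_threshold(PW = 0.21, params = ref_params, NoP = 1)
  expect_equal(as.numeric(a1), 0.62102, tolerance = 1e-4)
  a2 <- analytic_threshold(PW = 0.525, IPI = 20, params = ref_params, NoP = 2)
  expect_equal(as.numeric(a2), 0.252140, tolerance = 1e-4)
  expect_equal(attr(a2, "case"), "SPANNING_INTERVAL")
  a3 <- analytic_threshold(PW = 0.525, IPI = 50, params = ref_params, NoP = 2)
  expect_equal(as.numeric(a3), 0.255401, tolerance = 1e-4)
  expect_equal(attr(a3, "case"), "TWO_INTERVALS")
})

test_that("lambdaL * deltaT closes to log 2 at the analytic threshold in every case", {
  configs <- list(list(IPI = 20, p = ref_params),                 # case 3
                  list(IPI = 50, p = ref_params),                 # case 2
                  list(IPI = 20, p = lumped_params(lambdaL = 0.05)))  # case 1
  for (cf in configs) {
    a <- analytic_threshold(PW = 0.525, IPI = cf$IPI, params = cf$p, NoP = 2)
    sti <- supra_threshold_intervals(attr(a, "B"), cf$p$alphaL, cf$p$tau2,
                                     cf$IPI)
    expect_equal(sti$case, attr(a, "case"))
    expect_equal(cf$p$lambdaL * sti$deltaT, log(2), tolerance = 1e-12)
  }
})

test_that("supra-threshold durations are monotone in IPI within each case", {
  p <- ref_params
  B <- 1.5 * p$alphaL
  grid <- seq(3, 150, by = 0.5)
  res <- lapply(grid, supra_threshold_intervals, B = B, alphaL = p$alphaL,
                tau2 = p$tau2)
  case <- vapply(res, `[[`, "", "case")
  dT <- vapply(res, `[[`, 1, "deltaT")
  for (cs in unique(case)) {
    d <- diff(dT[case == cs])
    if (cs == "SPANNING_INTERVAL") expect_true(all(d > 0))
    else expect_true(all(d < 0))
  }
  expect_setequal(unique(case), c("SPANNING_INTERVAL", "TWO_INTERVALS"))
})

test_that("the analytic threshold is continuous across case boundaries", {
  eps <- 1e-7
  b <- case_boundaries(45, 0.01)
  expect_equal(as.numeric(analytic_threshold(0.525, b$IPI23 - eps, ref_params)),
               as.numeric(analytic_threshold(0.525, b$IPI23 + eps, ref_params)),
               tolerance = 1e-9)
  p5 <- lumped_params(lambdaL = 0.05)
  b5 <- case_boundaries(45, 0.05)
  expect_equal(as.numeric(analytic_threshold(0.525, b5$IPI21 - eps, p5)),
               as.numeric(analytic_threshold(0.525, b5$IPI21 + eps, p5)),
               tolerance = 1e-9)
})

test_that("threshold-IPI curves have the predicted shape dichotomy", {
  grid <- seq(5, 100, by = 1)
  cur <- threshold_curve(grid, 0.525, ref_params, mode = "analytic")
  d <- diff(cur$A50_mA)
  # exactly one interior extremum (a minimum) when lambdaL*tau2 < 1
  expect_equal(sum(diff(sign(d)) != 0), 1L)
  # discrete argmin lies within one step of the case-switch interval
  expect_lt(abs(grid[which.min(cur$A50_mA)] -
                  case_boundaries(45, 0.01)$IPI23), 1)
  p5 <- lumped_params(lambdaL = 0.05)
  cur5 <- threshold_curve(grid, 0.525, p5, mode = "analytic")
  expect_true(all(diff(cur5$A50_mA) > 0))  # no extremum above the product
})
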