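test_that("mono-exponential profile recovers its closed-form AUC and t1/2", {
  t <- c(0, 0.25, 0.5, 1, 1.5, 2, 3, 4, 6, 8, 12, 16, 24, 36, 48, 60, 72)
  r <- nca(t, 100 * exp(-0.1 * t), dose = 5, body_weight = 70)
  expect_equal(r$auc_inf, 1000, tolerance = 0.01)
  expect_equal(r$t_half, log(2) / 0.1, tolerance = 0.01)
  expect_equal(r$lambda_z, 0.1, tolerance = 1e-6)
})

test_that("bi-exponential profile recovers the analytic sum of C_i/lambda_i", {
  t <- c(0, 0.25, 0.5, 1, 1.5, 2, 3, 4, 6, 8, 12, 16, 24, 36, 48, 60, 72)
  conc <- 60 * exp(-1.2 * t) + 40 * exp(-0.06 * t)
  r <- nca(t, conc, dose = 5, body_weight = 70)
  expect_equal(r$auc_inf, 60 / 1.2 + 40 / 0.06, tolerance = 0.01)
  # clearance in mL/min/kg from dose/AUC
  expect_equal(r$cl, 5e6 / r$auc_inf / 60 / 70, tolerance = 1e-10)
  expect_equal(r$c_tend, conc[length(conc)])
})

test_that("AUC is insensitive to doubling the sampling density", {
  t1 <- c(0, 0.25, 0.5, 1, 1.5, 2, 3, 4, 6, 8, 12, 24, 48, 72)
  t2 <- sort(unique(c(t1, t1[-1] - diff(t1) / 2)))
  f <- function(t) 60 * exp(-1.2 * t) + 40 * exp(-0.06 * t)
  a1 <- nca(t1, f(t1))$auc_inf
  a2 <- nca(t2, f(t2))$auc_inf
  expect_lt(abs(a1 / a2 - 1), 0.01)
})

test_that("log-down trapezoid beats the linear rule on declining curves", {
  t <- c(1, 4, 8, 16, 24, 48, 72)
  conc <- 100 * exp(-0.15 * t)
  exact <- (100 / 0.15) * (exp(-0.15 * 1) - exp(-0.15 * 72))
  lin <- nca(t, conc, method = "linear")$auc_0_t
  log_down <- nca(t, conc)$auc_0_t
  expect_lt(abs(log_down - exact), abs(lin - exact))
  expect_equal(log_down, exact, tolerance = 1e-9)
})

test_that("non-declining terminal phase raises a diagnostic error", {
  t <- c(1, 2, 4, 8, 12, 24)
  conc <- c(10, 8, 6, 5, 6, 8)
  expect_error(nca(t, conc), "lambda_z")
  expect_error(nca(1:3, c(1, 2, 3)), "at least 4")
})

test_that("clearance recovered from a linear engine configuration", {
  # renal-filtration-only probe with forced unit partitioning: the true
  # plasma clearance is gfr_fraction * GFR exactly
  frac <- 0.005
  cmp <- probe_compound(gfr_fraction = frac)
  ph <- reference_individual()
  st <- default_settings(metabolic_scaling = 1, kp_override = 1,
                         output_resolution = 0.02)
  m <- pbpk_model(cmp, ph, dose_regimen("iv_bolus", 10), duration = 15000,
                  settings = st)
  sim <- simulate(m)
  grid <- seq(500, 15000, by = 500)
  r <- sim_nca(sim, grid, compound = "probe", dose = 10,
               body_weight = ph$body_weight)
  cl_true <- frac * ph$gfr / ph$body_weight   # mL/min/kg
  expect_equal(r$cl, cl_true, tolerance = 0.02)
})
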