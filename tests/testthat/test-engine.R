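test_that("no dose gives an identically zero trajectory", {
  m <- pbpk_model(hal_pair(), reference_individual(), dosing = list(),
                  duration = 12)
  sim <- simulate(m)
  expect_true(all(sim$conc[["haloperidol"]] == 0))
  expect_true(all(sim$state == 0))
})

test_that("mass balance closes to 0.1% at every checkpoint", {
  m <- pbpk_model(hal_pair(), reference_individual(),
                  dose_regimen("iv_bolus", 8.8), duration = 96)
  sim <- simulate(m)
  for (at in c(0.5, 2, 12, 48, 96)) {
    mb <- mass_balance(sim, at = at)
    expect_lt(abs(mb$total_fraction - 1), 0.001)
  }
})

test_that("metabolite formation is molar-stoichiometric with parent loss", {
  m <- pbpk_model(hal_pair(), reference_individual(),
                  dose_regimen("iv_bolus", 8.8), duration = 96)
  sim <- simulate(m)
  for (at in c(1, 6, 24, 96)) {
    mb <- mass_balance(sim, at = at)
    parent <- mb$compounds[["haloperidol"]]
    met <- mb$compounds[["reduced haloperidol"]]
    formed <- parent$pathways[["CBR1:reduction to reduced haloperidol"]]
    received <- met$body + met$lumen + met$renal +
      met$additional_clearance + sum(met$pathways) + met$feces
    expect_equal(received, unname(formed), tolerance = 1e-3)
  }
})

test_that("slow-elimination limit reproduces the one-compartment solution", {
  frac <- 0.005
  cmp <- probe_compound(gfr_fraction = frac)
  ph <- reference_individual()
  st <- default_settings(metabolic_scaling = 1, kp_override = 1,
                         output_resolution = 0.02)
  m <- pbpk_model(cmp, ph, dose_regimen("iv_bolus", 10), duration = 15000,
                  settings = st)
  sim <- simulate(m)
  V <- sum(ph$organs$volume) + sum(ph$blood)      # L
  k <- frac * ph$gfr * 60 / 1000 / V              # 1/h
  grid <- seq(log(2) / k, 10 * log(2) / k, length.out = 19)
  pred <- stats::approx(sim$times, sim$conc[["probe"]], grid)$y
  ref <- 10e6 / (V * 1000) * exp(-k * grid)       # ng/mL
  expect_lt(max(abs(pred / ref - 1)), 0.005)
})

test_that("exposure is dose-linear far below Km", {
  st <- default_settings()
  m1 <- halopbpk:::scenario_model("iv_2.5mg_healthy_47", st)
  s1 <- simulate(m1)
  m2 <- m1
  m2$dosing <- list(dose_regimen("iv_bolus", 5, compound = "haloperidol"))
  s2 <- simulate(m2)
  grid <- halopbpk:::.sampling_grid(0.5, "iv")
  a1 <- sim_nca(s1, grid)$auc_inf
  a2 <- sim_nca(s2, grid)$auc_inf
  expect_equal(a2 / a1, 2, tolerance = 0.01)
})

test_that("zero intestinal permeability gives zero bioavailability", {
  cmp <- probe_compound(p_int = 0)
  m <- pbpk_model(cmp, reference_individual(),
                  dose_regimen("oral", 10), duration = 96,
                  settings = default_settings(metabolic_scaling = 1,
                                              kp_override = 1))
  sim <- simulate(m)
  expect_lt(max(sim$conc[["probe"]]), 1e-10)
  mb <- mass_balance(sim)
  b <- mb$compounds[["probe"]]
  expect_equal(unname(b$lumen + b$feces), unname(b$dose_umol),
               tolerance = 1e-6)
  # most of the unabsorbed dose has left through the colonic sink by 96 h
  expect_gt(unname(b$feces) / unname(b$dose_umol), 0.9)
})

test_that("oral dosing shows a hepatic first pass (F < 1)", {
  ph <- reference_individual()
  st <- default_settings()
  base <- pbpk_model(hal_pair(), ph, dose_regimen("iv_bolus", 5),
                     duration = 96, settings = st)
  siv <- simulate(base)
  oral <- base
  oral$dosing <- list(dose_regimen("oral", 5, compound = "haloperidol"))
  soral <- simulate(oral)
  auc_iv <- auc_dense(siv)
  auc_oral <- auc_dense(soral)
  expect_gt(auc_oral, 0)
  expect_lt(auc_oral / auc_iv, 1)
})

test_that("absorptive area multiplier raises bioavailability monotonically", {
  ph <- reference_individual()
  aucs <- vapply(c(3, 9.5, 30), function(mult) {
    st <- default_settings(area_multiplier = mult)
    m <- pbpk_model(hal_pair(), ph, dose_regimen("oral", 10),
                    duration = 48, settings = st)
    auc_dense(simulate(m))
  }, numeric(1))
  expect_true(all(diff(aucs) > 0))
})

test_that("a CV = 0 population collapses onto the mean individual", {
  pop <- sample_population(3, weight_range = c(70, 70), age_range = c(30, 30),
                           cv = 0, seed = 1)
  m <- pbpk_model(hal_pair(), pop, dose_regimen("iv_bolus", 5),
                  duration = 24)
  psim <- simulate(m)
  ind <- reference_individual(age = 30, body_weight = 70)
  msim <- simulate(pbpk_model(hal_pair(), ind, dose_regimen("iv_bolus", 5),
                              duration = 24))
  b <- psim$bands[["haloperidol"]]
  expect_equal(b$p5, b$p95, tolerance = 1e-12)
  expect_equal(b$mean, msim$conc[["haloperidol"]], tolerance = 1e-9)
})

test_that("population simulation is byte-reproducible under a fixed seed", {
  run <- function() {
    pop <- sample_population(3, weight_range = c(60, 80), cv = 0.45,
                             seed = 77)
    m <- pbpk_model(hal_pair(), pop, dose_regimen("iv_bolus", 5),
                    duration = 24)
    simulate(m)$profiles
  }
  expect_identical(run(), run())
})

test_that("dose bookkeeping and dosing validation", {
  ph <- reference_individual(body_weight = 70.5)
  m <- pbpk_model(hal_pair(), ph, dose_regimen("iv_bolus", 0.125, "mg/kg"),
                  duration = 6)
  sim <- simulate(m)
  expect_equal(sim$engine$dose_umol[1], 0.125 * 70.5 / 376 * 1000,
               tolerance = 1e-12)
  expect_error(dose_regimen("iv_bolus", 0), "positive")
  expect_error(dose_regimen("iv_infusion", 5), "infusion_duration")
  expect_error(pbpk_model(haloperidol(), ph, dose_regimen("iv_bolus", 5)),
               "does not resolve")
  expect_error(pbpk_model(hal_pair(), ph,
                          dose_regimen("iv_bolus", 5, compound = "nope")),
               "unknown compound")
})
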