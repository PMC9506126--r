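test_that("reference individual is deterministic and self-consistent", {
  a <- reference_individual("male", 30, 70.5, 176)
  b <- reference_individual("male", 30, 70.5, 176)
  expect_identical(a, b)

  # total simulated volume tracks body volume (density ~ 1 kg/L)
  total <- sum(a$organs$volume) + sum(a$blood)
  expect_lt(abs(total - 70.5) / 70.5, 0.10)

  # flow conservation: organ perfusion sums to cardiac output, so venous
  # return equals cardiac output in every individual
  perf <- sum(a$organs$flow[a$organs$organ != "lung"])
  expect_equal(perf, a$cardiac_output, tolerance = 1e-2)
  lung <- a$organs$flow[a$organs$organ == "lung"]
  expect_equal(lung, a$cardiac_output)
})

test_that("organ volumes grow strictly with body weight", {
  small <- reference_individual(body_weight = 70.5)
  big <- reference_individual(body_weight = 141, override = TRUE)
  expect_true(all(big$organs$volume > small$organs$volume))
  expect_gt(big$gfr, small$gfr)
  expect_gt(big$cardiac_output, small$cardiac_output)
})

test_that("demographics outside the study range need an explicit override", {
  expect_error(reference_individual(age = 10), "adult range")
  expect_error(reference_individual(body_weight = 120), "43-92")
  expect_s3_class(reference_individual(body_weight = 120, override = TRUE),
                  "physiology")
})

test_that("plasma-protein scaling of fu: identity, closed form, monotone", {
  expect_equal(scale_fraction_unbound(0.085, 1), 0.085)
  # closed form fu / (fu + s (1 - fu))
  expect_equal(scale_fraction_unbound(0.085, 0.5), 0.085 / 0.5425,
               tolerance = 1e-12)
  s <- c(0.25, 0.5, 1, 2, 4, 8, 1e6)
  fus <- vapply(s, function(x) scale_fraction_unbound(0.085, x), numeric(1))
  expect_true(all(diff(fus) < 0))
  expect_lt(fus[length(fus)], 1e-5)
  expect_error(scale_fraction_unbound(0.085, 0), "positive")
  expect_error(scale_fraction_unbound(0, 1), "0, 1")
})

test_that("population sampling: zero variance, seed determinism", {
  p0 <- sample_population(20, cv = 0, seed = 11)
  mult <- do.call(rbind, lapply(p0, `[[`, "pathway_activity"))
  expect_true(all(mult == 1))

  p1 <- sample_population(50, cv = 0.45, seed = 42)
  p2 <- sample_population(50, cv = 0.45, seed = 42)
  expect_identical(population_table(p1), population_table(p2))
  p3 <- sample_population(50, cv = 0.45, seed = 43)
  expect_false(identical(population_table(p1), population_table(p3)))

  expect_error(sample_population(10, cv = -0.1, seed = 1), "non-negative")
  expect_error(sample_population(10, cv = 0.45), "seed")
})

test_that("sampled activity multipliers reproduce the configured CV", {
  pop <- sample_population(5000, cv = 0.45, seed = 7)
  mult <- do.call(rbind, lapply(pop, `[[`, "pathway_activity"))
  cv_hat <- apply(mult, 2, function(x) stats::sd(x) / mean(x))
  expect_true(all(abs(cv_hat / 0.45 - 1) < 0.05))
  # demographics stay inside the requested ranges
  bw <- vapply(pop, `[[`, numeric(1), "body_weight")
  expect_true(all(bw >= 56 & bw <= 92))
})

test_that("truncated-normal demography stays inside its range", {
  pop <- sample_population(200, weight_range = c(43, 92),
                           demography = "truncnorm", cv = 0, seed = 3)
  bw <- vapply(pop, `[[`, numeric(1), "body_weight")
  expect_true(all(bw >= 43 & bw <= 92))
})
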