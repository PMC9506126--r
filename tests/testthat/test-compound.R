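test_that("incubation-binding Km correction reproduces the input table", {
  expect_equal(correct_km(62, 0.35), 21.7)
  expect_equal(correct_km(80, 0.35), 28)
  expect_equal(correct_km(64, 0.35), 22.4)
  expect_equal(correct_km(123, 1), 123)
  expect_error(correct_km(-1, 0.35), "positive")
  expect_error(correct_km(62, 0), "0, 1")
  expect_error(correct_km(62, 1.2), "0, 1")
})

test_that("per-pmol Vmax conversion and cytosolic reference concentration", {
  expect_equal(convert_vmax_per_pmol(0.53, 460), 243.8)
  expect_equal(convert_vmax_per_pmol(0, 460), 0)
  expect_equal(convert_vmax_per_pmol(1, 1000), 1000)
  expect_error(convert_vmax_per_pmol(-0.1, 460), "non-negative")

  x <- cytosolic_reference_concentration(75, 75.4)
  expect_equal(as.numeric(x), 5.655)
  expect_equal(attr(x, "reported"), 5.6)  # two significant figures, cut
  expect_equal(as.numeric(cytosolic_reference_concentration(0, 75.4)), 0)
  expect_equal(as.numeric(cytosolic_reference_concentration(100, 50)), 5)
  expect_error(cytosolic_reference_concentration(-1), "non-negative")
})

test_that("ISEF scaling of recombinant rates", {
  expect_equal(apply_isef(600, 0.16), 96)
  expect_equal(apply_isef(2300, 0.06), 138)
  expect_equal(apply_isef(123.4, 1), 123.4)
  expect_error(apply_isef(600, 0), "0, 1")
  expect_error(apply_isef(600, 1.3), "0, 1")
  expect_error(apply_isef(-5, 0.5), "non-negative")
})

test_that("haloperidol parameter set matches the printed inputs", {
  hal <- haloperidol()
  expect_equal(hal$molecular_weight, 376)
  expect_equal(hal$effective_molecular_weight, 336.86)
  expect_equal(hal$log_p, 3.66)
  expect_equal(hal$pka, 8.65)
  expect_equal(hal$water_solubility, 0.0045)
  expect_equal(hal$fraction_unbound, 0.085)
  expect_equal(hal$intestinal_permeability, 3.09e-4)
  expect_equal(hal$fu_incubation, 0.35)
  expect_equal(hal$gfr_fraction, 1)
  expect_length(hal$pathways, 7)

  km <- vapply(hal$pathways, `[[`, numeric(1), "km")
  expect_equal(unname(km), c(21.7, 28, 88, 22.4, 61, 16, 64))
  cbr <- hal$pathways[["CBR1:reduction to reduced haloperidol"]]
  expect_equal(cbr$product, "reduced haloperidol")
  expect_equal(cbr$enzyme_content, 75)

  # every corrected Km reproduces fu_inc * apparent at the printed
  # precision, except the N-glucuronidation row which is loaded as printed
  for (p in hal$pathways) {
    if (is.na(p$km_apparent) || p$reaction == "N-glucuronidation") next
    expect_lte(abs(p$km - correct_km(p$km_apparent, 0.35)), 0.5)
  }
  # the optional correction flag applies it to the N-glucuronidation row
  hal2 <- haloperidol(correct_n_gluc_km = TRUE)
  expect_equal(hal2$pathways[["UGT1A4:N-glucuronidation"]]$km, 22.4)
})

test_that("internal rate unit is micromol/min/mg for every pathway", {
  hal <- haloperidol()
  v <- vapply(hal$pathways, `[[`, numeric(1), "vmax_umol_min_mg")
  expect_true(all(v > 0))
  expect_equal(unname(v),
               c(289e-6, 243.8e-6, 1.30e-3, 600 * 0.16 * 1e-6,
                 2300 * 0.06 * 1e-6, 1000 * 0.05 * 1e-6, 440 * 0.16 * 1e-6),
               tolerance = 1e-12)
})

test_that("reduced haloperidol parameter set matches the printed inputs", {
  rh <- reduced_haloperidol()
  expect_equal(rh$molecular_weight, 378)
  expect_equal(rh$log_p, 3.52)
  expect_equal(rh$fraction_unbound, 0.244)
  expect_equal(rh$water_solubility, 0.0131)
  expect_equal(rh$additional_hepatic_clearance, 5)
  expect_length(rh$pathways, 1)
  p <- rh$pathways[[1]]
  expect_equal(p$enzyme, "CYP3A4")
  expect_equal(p$km, 46)
  expect_equal(p$vmax, 98)
  expect_equal(p$product, "haloperidol")
})

test_that("compound serialization round-trips exactly", {
  for (cmp in hal_pair()) {
    path <- withr::local_tempfile(fileext = ".cfg")
    write_compound(cmp, path)
    back <- read_compound(path)
    expect_equal(back, cmp)
  }
})

test_that("packaged compound config files equal the constructors", {
  hal_cfg <- system.file("extdata", "haloperidol.cfg", package = "halopbpk")
  rh_cfg <- system.file("extdata", "reduced_haloperidol.cfg",
                        package = "halopbpk")
  expect_equal(read_compound(hal_cfg), haloperidol())
  expect_equal(read_compound(rh_cfg), reduced_haloperidol())
})

test_that("compound and pathway invariants are enforced", {
  expect_error(compound("x", 300, 350, 1, 8, 1, 0.5, 0), "molecular_weight")
  expect_error(compound("x", 300, 250, 1, 8, 1, 1.5, 0), "fraction_unbound")
  expect_error(compound("x", 300, 250, 1, 8, 1, 0.5, 0, gfr_fraction = 2),
               "gfr_fraction")
  expect_error(metabolic_pathway("CYP3A4", "r", "HLM", km_apparent = 10,
                                 km = 20, vmax = 1),
               "must not exceed")
  expect_error(metabolic_pathway("CYP3A4", "r", "HLM", km = -1, vmax = 1),
               "positive")
})
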