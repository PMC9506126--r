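# Shared fixtures for the test suite.

# A neutral, fully unbound probe compound: no metabolism, renal filtration
# only.  With a forced Kp of 1 the whole body collapses towards a single
# well-stirred compartment once elimination is slow against perfusion.
probe_compound <- function(gfr_fraction = 1, p_int = 0) {
  compound("probe", molecular_weight = 300, effective_molecular_weight = 250,
           log_p = 0, pka = 2, water_solubility = 1, fraction_unbound = 1,
           intestinal_permeability = p_int, gfr_fraction = gfr_fraction)
}

# The packaged parent-metabolite pair.
hal_pair <- function() list(haloperidol(), reduced_haloperidol())

# NCA of a simulation on a scenario-style sparse grid.
sim_nca <- function(sim, grid, compound = "haloperidol", dose = NA,
                    body_weight = NA) {
  conc <- stats::approx(sim$times, sim$conc[[compound]], xout = grid)$y
  nca(grid, conc, dose = dose, body_weight = body_weight)
}

# AUC(0-t_end) of a simulated profile on the dense output grid.
auc_dense <- function(sim, compound = "haloperidol") {
  conc <- sim$conc[[compound]]
  sum(diff(sim$times) * (head(conc, -1) + tail(conc, -1)) / 2)
}

# Independent single-purpose implementation of the tissue-composition
# partitioning equations for a monoprotic base (the oracle against which
# the package implementation is checked).  Written directly from the
# published equation set, organ by organ, without reusing package code.
oracle_kpu <- function(log_p, pka, fu, hematocrit, bp, f_ew, f_iw, f_nl,
                       f_np, ap) {
  P <- 10^log_p
  Pnp <- 0.3 * P + 0.7
  Y <- 1 + 10^(pka - 7.4)
  # blood-cell branch: Kpu_RBC from B:P, then solve for Ka_AP
  kpu_rbc <- (bp - (1 - hematocrit)) / (hematocrit * fu)
  Xr <- 1 + 10^(pka - 7.2)
  ka <- (kpu_rbc - (Xr / Y) * 0.603 -
           (P * 0.0017 + Pnp * 0.0029) / Y) * Y / (0.5 * 10^(pka - 7.2))
  X <- 1 + 10^(pka - 7.0)
  f_ew + (X / Y) * f_iw + ka * ap * 10^(pka - 7.0) / Y +
    (P * f_nl + Pnp * f_np) / Y
}
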