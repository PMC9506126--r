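pow10 <- function(x) 10^x

#' Tissue-to-plasma partition coefficients (Rodgers-Rowland, base scheme)
#'
#' Computes the tissue:plasma partition coefficient for every organ of a
#' physiology using the published tissue-composition scheme for moderate to
#' strong monoprotic bases (pKa > 7): ionization-corrected partitioning into
#' intracellular water (intracellular pH 7.0 vs plasma pH 7.4), neutral
#' lipid and neutral phospholipid partitioning driven by lipophilicity, and
#' electrostatic association of the cationic species with tissue acidic
#' phospholipids.  The acidic-phospholipid association constant is
#' back-calculated from blood-cell partitioning, which is itself derived
#' from the blood:plasma ratio (see [blood_plasma_ratio()]).
#'
#' @param compound A [compound()] object (treated as a monoprotic base).
#' @param physiology A [reference_individual()] object.
#' @param blood_plasma Blood:plasma concentration ratio used to derive the
#'   blood-cell partitioning.  Default 1.
#' @param ph_plasma,ph_iw Plasma and intracellular pH (defaults 7.4, 7.0).
#' @return Named numeric vector of Kp (tissue:plasma) per organ.
#' @export
partition_coefficients <- function(compound, physiology,
                                   blood_plasma = 1,
                                   ph_plasma = 7.4, ph_iw = 7.0) {
  stopifnot(inherits(compound, "compound"), inherits(physiology, "physiology"))
  comp <- physiology$tissue_composition
  fu <- compound$fraction_unbound
  kpu <- kpu_tissues(log_p = compound$log_p, pka = compound$pka, fu = fu,
                     hematocrit = physiology$hematocrit,
                     composition = comp, blood_plasma = blood_plasma,
                     ph_plasma = ph_plasma, ph_iw = ph_iw)
  stats::setNames(fu * kpu, comp$organ)
}

# Kpu (tissue : unbound plasma) for all organs in `composition`.
kpu_tissues <- function(log_p, pka, fu, hematocrit, composition,
                        blood_plasma = 1, ph_plasma = 7.4, ph_iw = 7.0) {
  P <- pow10(log_p)
  Pnp <- 0.3 * P + 0.7                    # neutral phospholipid partition
  Y <- 1 + pow10(pka - ph_plasma)           # plasma ionization
  X <- 1 + pow10(pka - ph_iw)               # intracellular ionization
  ka_ap <- acidic_phospholipid_ka(log_p, pka, fu, hematocrit,
                                  blood_plasma, ph_plasma)
  composition$f_ew +
    (X / Y) * composition$f_iw +
    (ka_ap * composition$ap * pow10(pka - ph_iw)) / Y +
    (P * composition$f_nl + Pnp * composition$f_np) / Y
}

# Association constant of the cationic drug with acidic phospholipids,
# back-calculated from blood-cell partitioning: Kpu_RBC is obtained from
# the blood:plasma ratio and haematocrit, then the RBC composition equation
# is solved for Ka_AP.
acidic_phospholipid_ka <- function(log_p, pka, fu, hematocrit,
                                   blood_plasma = 1, ph_plasma = 7.4) {
  rbc <- .rbc_composition
  kpu_rbc <- (blood_plasma - (1 - hematocrit)) / (hematocrit * fu)
  P <- pow10(log_p)
  Pnp <- 0.3 * P + 0.7
  Y <- 1 + pow10(pka - ph_plasma)
  X <- 1 + pow10(pka - rbc$ph)
  resid <- kpu_rbc - (X / Y) * rbc$f_iw -
    (P * rbc$f_nl + Pnp * rbc$f_np) / Y
  ka <- resid * Y / (rbc$ap * pow10(pka - rbc$ph))
  max(ka, 0)
}

#' Blood:plasma concentration ratio
#'
#' The model's blood:plasma ratio.  By default a configured constant of 1 is
#' used (no preferential erythrocyte distribution); passing a measured or
#' assumed ratio propagates consistently through partitioning, because the
#' acidic-phospholipid association constant is derived from the same value.
#'
#' @param compound A [compound()] object (reserved for compound-specific
#'   measured ratios).
#' @param value The configured ratio (default 1).
#' @return The blood:plasma ratio.
#' @export
blood_plasma_ratio <- function(compound, value = 1) {
  value
}
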