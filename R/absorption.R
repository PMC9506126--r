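# Compartmental gut-lumen model constants.
#
# Stomach plus seven small-intestinal segments plus colon.  First-order
# gastric emptying with a 15-min half-life; total small-intestinal transit
# 3.3 h split evenly over the seven segments; slow colonic exit to a faecal
# sink.  Per-segment absorption is permeability-limited:
#   rate = P_int [cm/h] * (S/V)_geom [1/cm] * area_multiplier * A_dissolved,
# with the geometric surface-to-volume ratio of a cylinder (2/r, radius
# 1.25 cm small intestine, 2.5 cm colon) and a global mucosal amplification
# multiplier (folds and villi) from the settings.  Dissolution is
# first-order with a Henderson-Hasselbalch solubility cap per segment
# (monoprotic base: S(pH) = S_neutral * (1 + 10^(pKa - pH)), capped at
# 10^6-fold ionization gain).
.gi <- list(
  k_stomach = log(2) / 0.25,   # gastric emptying, 1/h
  n_si = 7L,
  k_si = 7 / 3.3,              # per-segment small-intestinal transit, 1/h
  k_colon = 1 / 24,            # colonic exit to faeces, 1/h
  k_diss = 18,                 # first-order dissolution, 1/h
  sv_si = 2 / 1.25,            # geometric S/V, 1/cm
  sv_colon = 2 / 2.5,
  colon_amp_frac = 0.1,        # colonic mucosal amplification vs SI
  ph = c(stomach = 1.5, si1 = 6.0, si2 = 6.2, si3 = 6.4, si4 = 6.6,
         si5 = 6.8, si6 = 7.0, si7 = 7.2, colon = 6.5),
  fluid = c(stomach = 0.25, si1 = 0.07, si2 = 0.07, si3 = 0.07, si4 = 0.07,
            si5 = 0.07, si6 = 0.07, si7 = 0.07, colon = 0.2)  # L
)

# Solubility cap per lumen segment in µmol, for a monoprotic base.
lumen_solubility_caps <- function(compound) {
  gain <- pmin(10^(compound$pka - .gi$ph), 1e6)
  s_mg_ml <- compound$water_solubility * (1 + gain)
  s_mg_ml * 1000 * .gi$fluid / compound$molecular_weight * 1000  # µmol
}

# Per-segment absorption rate constants (1/h): 7 SI values then colon.
lumen_absorption_rates <- function(compound, area_multiplier) {
  p_cm_h <- compound$intestinal_permeability * 60
  ka_si <- p_cm_h * .gi$sv_si * area_multiplier
  ka_colon <- p_cm_h * .gi$sv_colon * area_multiplier * .gi$colon_amp_frac
  c(rep(ka_si, .gi$n_si), ka_colon)
}
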