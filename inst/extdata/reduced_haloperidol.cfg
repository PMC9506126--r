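name = reduced haloperidol
molecular_weight = 3.78e+02
effective_molecular_weight = 3.39e+02
log_p = 3.52e+00
pka = 8.6600000000000001e+00
water_solubility = 1.3100000000000001e-02
fraction_unbound = 2.4399999999999999e-01
intestinal_permeability = 2.0799999999999999e-04
gfr_fraction = 1e+00
fu_incubation = NA
additional_hepatic_clearance = 5e+00
[pathway]
enzyme = CYP3A4
reaction = oxidation to haloperidol
system = HLM
km_apparent = NA
km = 4.6e+01
vmax = 9.8e+01
vmax_unit = pmol/min/mg
isef = NA
localization = microsomal
enzyme_content = NA
product = haloperidol
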