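name = haloperidol
molecular_weight = 3.76e+02
effective_molecular_weight = 3.3686000000000001e+02
log_p = 3.6600000000000001e+00
pka = 8.6500000000000004e+00
water_solubility = 4.4999999999999997e-03
fraction_unbound = 8.5000000000000006e-02
intestinal_permeability = 3.0899999999999998e-04
gfr_fraction = 1e+00
fu_incubation = 3.4999999999999998e-01
additional_hepatic_clearance = 0e+00
[pathway]
enzyme = CYP3A4
reaction = N-dealkylation to 4-FBPA
system = HLM
km_apparent = 6.2e+01
km = 2.1699999999999999e+01
vmax = 2.89e+02
vmax_unit = pmol/min/mg
isef = NA
localization = microsomal
enzyme_content = NA
product = sink
[pathway]
enzyme = CYP3A4
reaction = oxidation to HPP+
system = HLM
km_apparent = 8e+01
km = 2.8e+01
vmax = 2.4380000000000001e+02
vmax_unit = pmol/min/mg
isef = NA
localization = microsomal
enzyme_content = NA
product = sink
[pathway]
enzyme = CBR1
reaction = reduction to reduced haloperidol
system = HLC
km_apparent = 2.5e+02
km = 8.8e+01
vmax = 1.3e+00
vmax_unit = nmol/min/mg
isef = NA
localization = cytosolic
enzyme_content = 7.5e+01
product = reduced haloperidol
[pathway]
enzyme = UGT1A4
reaction = O-glucuronidation
system = recombinant
km_apparent = 6.4e+01
km = 2.2399999999999999e+01
vmax = 6e+02
vmax_unit = pmol/min/mg
isef = 1.6e-01
localization = microsomal
enzyme_content = 3.3e+01
product = sink
[pathway]
enzyme = UGT1A9
reaction = O-glucuronidation
system = recombinant
km_apparent = 1.74e+02
km = 6.1e+01
vmax = 2.3e+03
vmax_unit = pmol/min/mg
isef = 5.9999999999999998e-02
localization = microsomal
enzyme_content = 2.2699999999999999e+01
product = sink
[pathway]
enzyme = UGT2B7
reaction = O-glucuronidation
system = recombinant
km_apparent = 4.5e+01
km = 1.6e+01
vmax = 1e+03
vmax_unit = pmol/min/mg
isef = 5.0000000000000003e-02
localization = microsomal
enzyme_content = 6.9400000000000006e+01
product = sink
[pathway]
enzyme = UGT1A4
reaction = N-glucuronidation
system = recombinant
km_apparent = 6.4e+01
km = 6.4e+01
vmax = 4.4e+02
vmax_unit = pmol/min/mg
isef = 1.6e-01
localization = microsomal
enzyme_content = 3.3e+01
product = sink
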