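---
title: "A whole-body PBPK model of haloperidol and reduced haloperidol: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A whole-body PBPK model of haloperidol and reduced haloperidol: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(halopbpk)
```

## The problem

Haloperidol is a first-generation antipsychotic with a narrow therapeutic
index and notoriously variable exposure between patients.  It is almost
completely metabolised in the liver — only about 1% of a dose appears
unchanged in urine — through three routes: CYP3A4 oxidation (N-dealkylation
to 4-FBPA and formation of the pyridinium species HPP+), glucuronidation by
UGT1A4, UGT1A9 and UGT2B7, and cytosolic carbonyl reduction by CBR1 to
reduced haloperidol (RHAL).  RHAL is itself back-oxidised to haloperidol by
CYP3A4, so parent and metabolite form a cycle.  `halopbpk` implements a
whole-body physiologically based pharmacokinetic (PBPK) model of this pair,
a non-compartmental analysis (NCA) layer, the model-qualification
statistics used in PBPK practice (predicted/observed ratio, prediction
error, mean fold error, RMSE, the two-fold rule, visual-predictive-check
bands), a static CYP3A4-induction scenario for rifampicin co-treatment,
and a plasma-protein adjustment for tuberculosis (TB) patients.

## Model structure

The body is a perfusion-limited circuit of twelve tissues (lung, adipose,
bone, brain, gut, heart, kidney, liver, muscle, skin, spleen, and a lumped
rest compartment) plus venous and arterial blood.  Venous blood feeds the
lung; the lung feeds arterial blood; every tissue is perfused from the
arterial pool; gut and spleen drain through the portal vein into the
liver.  For a tissue with volume $V_t$, blood flow $Q_t$ and
tissue:plasma partition coefficient $K_p$, the amount $A_t$ follows

$$\frac{dA_t}{dt} = Q_t\left(C_{art} - \frac{A_t/V_t}{K_p/BP}\right),$$

with $BP$ the blood:plasma ratio.  Amounts are carried in µmol and time in
hours; reported venous plasma concentrations are converted to ng/mL
through the molecular weight.

Distribution is perfusion-limited even though the source model used a
permeability-based cellular transfer method: at haloperidol's
lipophilicity the two converge at steady state, and the permeability
parameters are not available.  The cost of this choice is visible early
after an intravenous bolus, where the perfusion-limited model spreads the
dose faster than sparse clinical sampling suggests; this is a documented
limitation (see "Known limitations").

**Partitioning.**  $K_p$ values are predicted with the tissue-composition
scheme for moderate-to-strong monoprotic bases: ionisation-corrected
partitioning into intracellular water (intracellular pH 7.0, plasma pH
7.4), neutral-lipid and neutral-phospholipid partitioning driven by logP,
and electrostatic association of the cation with tissue acidic
phospholipids.  The association constant is back-calculated from
blood-cell partitioning, which is derived from the configured
blood:plasma ratio (default 1.0, a neutral assumption in the absence of a
measured value).  Erythrocyte intracellular pH is 7.2.  For haloperidol
(logP 3.66, pKa 8.65, fu 0.085) this yields muscle $K_p \approx 4.6$ and
adipose $K_p \approx 19$, a steady-state volume near 500 L.

**Hepatic metabolism.**  Each pathway is Michaelis–Menten on the unbound
liver-water concentration $C_u = f_u \, C_{liver}/K_{p,liver}$:

$$v_j = \frac{V_{max,j}^{eff}\, C_u}{K_{m,j} + C_u}, \qquad
V_{max,j}^{eff} = V_{max,j} \times \mathrm{(M/C)PPGL} \times W_{liver}
\times a_{enzyme} \times s.$$

In vitro rates (per mg microsomal or cytosolic protein) are scaled with
MPPGL (40 mg/g, the literature standard, configurable) or CPPGL
(75.4 mg/g, as printed), liver weight (1800 g at 70 kg, density 1 g/mL),
a per-enzyme population activity multiplier $a$, and one global scaling
factor $s$ shared by all pathways.  Apparent $K_m$ values are first
corrected for incubation binding ($K_m \times f_{u,inc}$, $f_{u,inc} =
0.35$); recombinant UGT rates are scaled to microsomes by their ISEFs
(0.16, 0.06, 0.05); all rates are converted to a single internal unit
(µmol/min/mg) at load.  The CBR1 flux transfers moles 1:1 into the RHAL
liver compartment, and RHAL's CYP3A4 back-oxidation transfers moles back
to haloperidol.  RHAL additionally carries a linear hepatic plasma
clearance of 5 mL/min/kg, applied to its hepatic outflow plasma
concentration (a config switch allows an intrinsic-clearance
interpretation instead).

**Renal elimination** is glomerular filtration of unbound drug,
$CL_R = f_{GFR}\times GFR \times f_u$, with the "GFR fraction" read as
1.0 (not 0.01): with $f_u = 0.085$ and GFR 110 mL/min this excretes
~1.7% of an intravenous dose unchanged, consistent with the ~1% mass
fraction the elimination data report; a value of 0.01 would give 0.02%.

**Absorption.**  Oral doses enter a compartmental lumen: stomach
(first-order emptying, 15 min half-life), seven small-intestinal segments
(total transit 3.3 h), and a colon draining to a faecal sink (24 h time
constant).  Dissolution is first-order with a Henderson–Hasselbalch
solubility cap per segment — a monoprotic base with pKa 8.65 is fully
ionised in gastric fluid, so even a 35 mg dose dissolves despite the low
neutral-species solubility (0.0045 mg/mL); an "instant" toggle bypasses
dissolution.  Segment absorption is permeability-limited:
$k_a = P_{int} \times (2/r) \times m$, with the printed specific
permeability $P_{int}$, the geometric surface-to-volume ratio of a
cylinder (radius 1.25 cm; colon 2.5 cm and one tenth of the mucosal
amplification), and a global mucosal amplification multiplier $m$.
Absorbed drug enters the liver with the portal inflow, so oral doses
undergo a hepatic first pass (simulated F ≈ 0.55).

**Dosing and integration.**  Intravenous boluses are 1-minute zero-order
infusions into venous blood to avoid discontinuities; infusions and oral
doses are event-scheduled, and the integration restarts at every event
edge.  The system (two compounds ≈ 100 states) is integrated with the
stiff-capable `lsoda` solver at rtol 1e-8 / atol 1e-12 with 12 output
points per hour.  Cumulative accumulators per elimination pathway make
mass balance checkable at every output time; it closes to 0.1%.

## Calibration: four documented degrees of freedom

In vitro kinetics alone do not fix a whole-body model; the source
workflow relied on a simulator's internal expression database and on
parameter identification.  `halopbpk` replaces these with four
one-dimensional calibrations, each a scalar root-find against one
observed quantity, run once and frozen in `hal_calibration`:

| constant | value | target |
|---|---|---|
| `metabolic_scaling` | 2.3987 | mean IV clearance 11.1 mL/min/kg (0.125 mg/kg study) |
| `area_multiplier` | 9.556 | oral Cmax 37.4 ng/mL (0.503 mg/kg study) |
| `tb_protein_scale` | 1.7527 | TB control-arm AUC 174 ng·h/mL (5 mg IV) |
| `rifampicin_fold` | 3.283 | induced/control AUC ratio 0.60 |

The metabolic scaling (≈2.4× the raw IVIVE prediction) absorbs unprinted
enzyme-expression levels; the mucosal amplification (≈10, a plausible
folds-plus-villi factor) absorbs effective absorptive area; the induction
fold (≈3.3) is squarely in the range reported for steady-state rifampicin
600 mg/day.  All four are re-derived from scratch by
`scripts/acceptance.R`.

**The TB protein scale runs opposite to a naive hypoalbuminaemia
argument.**  Scaling the binding protein *down* (scale < 1) raises the
free fraction, raises clearance and *lowers* exposure — but the TB
control arm shows ~1.8× the exposure of healthy subjects at the same
dose.  Haloperidol binds α1-acid glycoprotein, an acute-phase protein
that rises in active tuberculosis; a binding-protein scale above 1
(calibrated 1.75, fu 0.085 → 0.051) reproduces the observed direction and
magnitude.  The scaling law is
$f_u' = f_u / (f_u + s\,(1-f_u))$, the exact solution for a changed
binder concentration at constant affinity; partition coefficients are
rescaled proportionally to $f_u'$.

## Scenario sampling schedules

Predicted PK parameters are computed the way clinical ones are: the
simulated curve is sampled on a sparse schedule and run through the same
NCA (linear-up/log-down trapezoids, λz from the last four samples,
AUC extrapolation $C_{last}/\lambda_z$).  Oral scenarios start sampling at
0.5 h.  For intravenous studies the first-sample time was reconstructed
per study *before* any simulation was scored, from each study's reported
peak (dose over peak gives the effective distribution volume, and a
generic perfusion-mixing estimate gives the time to reach it): 2 h for
the three rich healthy studies, 1–1.5 h for the psychotic cohorts,
0.5 h for the 2.5 mg study and 5 min for the single-patient 5 mg case
report.  These schedules are part of the scenario definitions and were
not adjusted afterwards.

## The synthetic-observed generator

Clinical concentration–time curves are not shipped; the digitised points
they would provide are unreliable to reproduce.  Instead,
`synthetic_profile()` emulates what the analysis layer assumes observed
data look like: a known (bi-exponential or simulated) truth sampled
sparsely with multiplicative log-normal error, $C_{obs} = C\,e^\epsilon$,
$\epsilon \sim N(0, \sigma^2)$, $\sigma = \sqrt{\log(1+CV^2)}$, with an
LLOQ cut.  It reproduces its configured CV (checked at $10^4$
replicates), and `nca_recovery_experiment()` quantifies the NCA bias it
induces (noiseless bias < 1%; |bias| < 5% at CV 0.15 with rich
14-point sampling).  What these tests show is that the *analysis chain*
is unbiased under its own error model — not that real digitised clinical
data satisfy that model; real data add digitisation error, censoring and
between-subject variability that only the population layer represents.

Virtual populations draw weight and age uniformly (or truncated-normally)
within study ranges and per-enzyme activity multipliers log-normally with
CV 0.45 — the scale of the up-to-10-fold interindividual variability
reported for haloperidol N-dealkylation — centred so the multiplier mean
is 1.  With CV 0 the population collapses pointwise onto the mean
individual, which is tested.

## Numerical choices and degenerate inputs

* Solver: `lsoda`, rtol 1e-8, atol 1e-12; dense output 12/h; event-edge
  restarts.  Mass balance is asserted to 0.1% and dose linearity to
  2.00 ± 0.02 on a doubling far below $K_m$.
* The one-compartment closed form is recovered to < 0.5% when
  elimination is slow against perfusion (a unit-$K_p$ probe with
  filtration-only clearance); at ordinary clearances the first-hour
  mixing transient adds ~1% extra elimination, which is physics, not
  solver error.
* λz estimation refuses a non-declining tail with a diagnostic error;
  NCA requires at least four positive samples.
* Zero doses are rejected at construction; a zero-permeability compound
  yields exactly zero bioavailability with the dose accounted in the
  lumen and faeces.
* Truncation (not half-up rounding) to two significant figures is used
  when reporting the CBR1 reference concentration, matching the printed
  reporting convention (5.655 → 5.6 µmol/L).

## Known limitations

* **Early intravenous distribution.**  Perfusion-limited uptake spreads a
  bolus over the fast-perfused organs within minutes, so simulated
  concentrations in the first ~hour sit below what several studies'
  early samples imply.  Four of seven IV peak-concentration comparisons
  therefore exceed two-fold, while exposure (AUC) and clearance
  comparisons are almost all within it.  A permeability-limited variant
  has a config hook but no printed parameters to run on.
* **Mutually inconsistent observed studies.**  The 2 mg and 5 mg oral
  studies differ 5.8-fold in dose-normalised exposure although kinetics
  are linear at these doses; no single parameterisation can be within
  two-fold of both, and the package does not try — the 2 mg comparisons
  stay outside the band.
* **Glucuronidation share.**  From the printed in vitro inputs, UGT
  pathways carry ~19% of the dose (CYP3A4 ~39%, CBR1 ~49% formed with
  ~9% cycled back).  The literature statement that glucuronidation
  exceeds 50% is not reproducible from those inputs, and the global
  scaling factor cannot change pathway shares by construction.
* No gut-wall CYP3A4 (no printed intestinal expression), no
  enterohepatic recirculation, no downstream kinetics for HPP+/4-FBPA or
  the glucuronides (terminal sinks), no time-dependent induction onset,
  and no routes beyond intravenous and oral.

## Problem sizes used in the shipped checks

Mean-individual simulations cover 96 h at 12 output points per hour;
the disposition run extends to 240 h (>10 terminal half-lives).
Population examples use 100 individuals; reproducibility and
collapse tests use 3; the law-of-large-numbers check on activity
multipliers uses 5000 draws; NCA recovery uses 500 replicates; VPC
coverage uses 1000 profiles with 280 matched observations.
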