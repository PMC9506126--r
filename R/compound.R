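#' Correct an apparent Michaelis constant for non-specific incubation binding
#'
#' Apparent \eqn{K_m} values measured in microsomal or cytosolic incubations
#' overestimate the unbound affinity constant when the drug binds
#' non-specifically to incubation protein and lipid.  The unbound (corrected)
#' constant is the apparent value multiplied by the fraction unbound in the
#' incubation, \eqn{K_{m,u} = K_m \times f_{u,inc}}.
#'
#' @param km_apparent Apparent Michaelis constant (µmol/L), > 0.
#' @param fu_incubation Fraction unbound in the in vitro incubation, in (0, 1].
#' @return Corrected Michaelis constant (µmol/L).
#' @examples
#' correct_km(62, 0.35)  # 21.7
#' @export
correct_km <- function(km_apparent, fu_incubation) {
  if (any(km_apparent <= 0)) {
    stop("'km_apparent' must be positive", call. = FALSE)
  }
  if (any(fu_incubation <= 0) || any(fu_incubation > 1)) {
    stop("'fu_incubation' must be in (0, 1]", call. = FALSE)
  }
  km_apparent * fu_incubation
}

#' Convert a per-pmol-enzyme Vmax to a per-mg-microsomal-protein Vmax
#'
#' Turnover rates reported per pmol of CYP enzyme are converted to the
#' per-mg-microsomal-protein basis used by the model by multiplying with the
#' microsomal CYP content (pmol enzyme per mg microsomal protein).
#'
#' @param vmax_per_pmol Maximum rate in pmol/min/pmol enzyme, >= 0.
#' @param cyp_content Microsomal CYP content in pmol/mg protein, >= 0.
#' @return Vmax in pmol/min/mg microsomal protein.
#' @examples
#' convert_vmax_per_pmol(0.53, 460)  # 243.8
#' @export
convert_vmax_per_pmol <- function(vmax_per_pmol, cyp_content) {
  if (any(vmax_per_pmol < 0) || any(cyp_content < 0)) {
    stop("inputs must be non-negative", call. = FALSE)
  }
  vmax_per_pmol * cyp_content
}

#' Reference concentration of a cytosolic enzyme in whole liver
#'
#' Converts a cytosolic protein content (pmol enzyme per mg cytosolic
#' protein) to a whole-liver reference concentration in µmol/L, using the
#' cytosolic protein yield per gram of liver and a liver density of 1 g/mL:
#' content × CPPGL / 1000.
#'
#' @param content Enzyme content, pmol per mg cytosolic protein, >= 0.
#' @param cppgl Cytosolic protein per gram liver (mg/g), >= 0.  Default 75.4.
#' @return Reference concentration in µmol/L (unrounded).  The value cut to
#'   two significant figures (truncated, the reporting convention of the
#'   source data) is attached as attribute `"reported"`.
#' @examples
#' cytosolic_reference_concentration(75, 75.4)  # 5.655, reported 5.6
#' @export
cytosolic_reference_concentration <- function(content, cppgl = 75.4) {
  if (any(content < 0) || any(cppgl < 0)) {
    stop("inputs must be non-negative", call. = FALSE)
  }
  x <- content * cppgl / 1000
  reported <- if (x > 0) {
    scale <- 10^(1 - floor(log10(x)))
    floor(x * scale) / scale
  } else x
  structure(x, reported = reported)
}

#' Scale a recombinant-system Vmax to the liver-microsome system
#'
#' Applies an intersystem extrapolation factor (ISEF) to a maximum rate
#' measured with a recombinant enzyme so that it refers to human liver
#' microsomes: \eqn{V_{max,HLM} = V_{max,rec} \times ISEF}.
#'
#' @param vmax_recombinant Vmax from the recombinant system
#'   (pmol/min/mg protein), >= 0.
#' @param isef Intersystem extrapolation factor, in (0, 1].
#' @return Scaled Vmax (pmol/min/mg microsomal protein).
#' @examples
#' apply_isef(600, 0.16)  # 96
#' @export
apply_isef <- function(vmax_recombinant, isef) {
  if (any(vmax_recombinant < 0)) {
    stop("'vmax_recombinant' must be non-negative", call. = FALSE)
  }
  if (any(isef <= 0) || any(isef > 1)) {
    stop("'isef' must be in (0, 1]", call. = FALSE)
  }
  vmax_recombinant * isef
}

#' Describe one metabolic pathway of a compound
#'
#' @param enzyme Enzyme name ("CYP3A4", "CBR1", "UGT1A4", "UGT1A9", "UGT2B7").
#' @param reaction Short reaction label, e.g. "N-dealkylation to 4-FBPA".
#' @param system In vitro system the kinetics come from: "HLM", "HLC" or
#'   "recombinant".
#' @param km_apparent Apparent Michaelis constant (µmol/L), or `NA` when only
#'   the corrected value is known.
#' @param km Corrected (unbound) Michaelis constant (µmol/L).
#' @param vmax Maximum rate, in the unit given by `vmax_unit`.
#' @param vmax_unit `"pmol/min/mg"` or `"nmol/min/mg"` protein.
#' @param isef Intersystem extrapolation factor applied to `vmax`
#'   (recombinant systems only), or `NA`.
#' @param localization `"microsomal"` or `"cytosolic"`: which hepatic protein
#'   fraction carries the enzyme, hence whether MPPGL or CPPGL scales it.
#' @param enzyme_content Enzyme content in pmol per mg of that protein
#'   fraction (informational; kept for reporting).
#' @param product Name of the compound formed, or `"sink"` for terminal
#'   metabolite pools that the model does not follow further.
#' @return An object of class `"metabolic_pathway"`.  `$vmax_umol_min_mg` is
#'   the ISEF-scaled maximum rate converted to µmol/min/mg protein, the
#'   single internal rate unit of the model.
#' @export
metabolic_pathway <- function(enzyme, reaction, system,
                              km_apparent = NA_real_, km,
                              vmax, vmax_unit = c("pmol/min/mg", "nmol/min/mg"),
                              isef = NA_real_,
                              localization = c("microsomal", "cytosolic"),
                              enzyme_content = NA_real_,
                              product = "sink") {
  vmax_unit <- match.arg(vmax_unit)
  localization <- match.arg(localization)
  if (km <= 0) stop("'km' must be positive", call. = FALSE)
  if (!is.na(km_apparent) && km > km_apparent + 1e-9) {
    stop("corrected km must not exceed the apparent km", call. = FALSE)
  }
  if (vmax < 0) stop("'vmax' must be non-negative", call. = FALSE)
  v <- if (is.na(isef)) vmax else apply_isef(vmax, isef)
  # to µmol/min/mg protein
  scale <- switch(vmax_unit, "pmol/min/mg" = 1e-6, "nmol/min/mg" = 1e-3)
  structure(
    list(enzyme = enzyme, reaction = reaction, system = system,
         km_apparent = km_apparent, km = km,
         vmax = vmax, vmax_unit = vmax_unit, isef = isef,
         vmax_umol_min_mg = v * scale,
         localization = localization, enzyme_content = enzyme_content,
         product = product),
    class = "metabolic_pathway"
  )
}

#' Construct a compound parameter set
#'
#' Bundles the physicochemical, binding, absorption and metabolic parameters
#' that the PBPK engine needs for one drug.
#'
#' @param name Compound name.
#' @param molecular_weight Molecular weight (g/mol).
#' @param effective_molecular_weight Effective molecular weight used for
#'   permeability considerations (g/mol); must be below `molecular_weight`.
#' @param log_p Lipophilicity (log10 octanol:water partition coefficient).
#' @param pka Acid dissociation constant of the conjugate acid; the model
#'   treats every compound as a monoprotic base.
#' @param water_solubility Aqueous solubility of the neutral species (mg/mL).
#' @param fraction_unbound Fraction unbound in plasma, in (0, 1].
#' @param intestinal_permeability Specific intestinal permeability (cm/min).
#' @param gfr_fraction Fraction of the glomerular filtration of unbound drug
#'   that appears in urine (1 = filtered unbound drug is fully excreted).
#' @param fu_incubation Fraction unbound in in vitro incubations (used to
#'   correct apparent Km values).
#' @param pathways List of [metabolic_pathway()] objects.
#' @param additional_hepatic_clearance Linear hepatic plasma clearance not
#'   attributed to a named enzyme (mL/min/kg); 0 if absent.
#' @return An object of class `"compound"`.
#' @seealso [haloperidol()], [reduced_haloperidol()]
#' @export
compound <- function(name, molecular_weight, effective_molecular_weight,
                     log_p, pka, water_solubility, fraction_unbound,
                     intestinal_permeability, gfr_fraction = 1,
                     fu_incubation = NA_real_, pathways = list(),
                     additional_hepatic_clearance = 0) {
  stopifnot(molecular_weight > effective_molecular_weight,
            effective_molecular_weight > 0,
            water_solubility > 0,
            intestinal_permeability >= 0,
            additional_hepatic_clearance >= 0)
  if (fraction_unbound <= 0 || fraction_unbound > 1) {
    stop("'fraction_unbound' must be in (0, 1]", call. = FALSE)
  }
  if (gfr_fraction < 0 || gfr_fraction > 1) {
    stop("'gfr_fraction' must be in [0, 1]", call. = FALSE)
  }
  if (length(pathways) &&
      !all(vapply(pathways, inherits, logical(1), "metabolic_pathway"))) {
    stop("'pathways' must be a list of metabolic_pathway objects",
         call. = FALSE)
  }
  names(pathways) <- vapply(pathways, function(p) {
    paste(p$enzyme, p$reaction, sep = ":")
  }, character(1))
  structure(
    list(name = name,
         molecular_weight = molecular_weight,
         effective_molecular_weight = effective_molecular_weight,
         log_p = log_p, pka = pka,
         water_solubility = water_solubility,
         fraction_unbound = fraction_unbound,
         intestinal_permeability = intestinal_permeability,
         gfr_fraction = gfr_fraction,
         fu_incubation = fu_incubation,
         pathways = pathways,
         additional_hepatic_clearance = additional_hepatic_clearance),
    class = "compound"
  )
}

#' @export
print.compound <- function(x, ...) {
  cat("<compound>", x$name, "\n")
  cat(sprintf("  MW %g (effective %g) g/mol, logP %g, pKa %g (base)\n",
              x$molecular_weight, x$effective_molecular_weight,
              x$log_p, x$pka))
  cat(sprintf("  solubility %g mg/mL, fu %.3f, P_int %.3g cm/min, GFR fraction %g\n",
              x$water_solubility, x$fraction_unbound,
              x$intestinal_permeability, x$gfr_fraction))
  if (x$additional_hepatic_clearance > 0) {
    cat(sprintf("  additional hepatic clearance %g mL/min/kg\n",
                x$additional_hepatic_clearance))
  }
  if (length(x$pathways)) {
    cat("  pathways:\n")
    for (p in x$pathways) {
      cat(sprintf("    %-7s %-32s Km %6.3g umol/L  Vmax %.4g umol/min/mg (%s) -> %s\n",
                  p$enzyme, p$reaction, p$km, p$vmax_umol_min_mg,
                  p$localization, p$product))
    }
  }
  invisible(x)
}

#' The haloperidol parameter set
#'
#' Full drug-dependent parameterization of haloperidol: physicochemistry,
#' plasma and incubation binding, intestinal permeability, renal filtration,
#' and six hepatic pathways — two CYP3A4 oxidations (N-dealkylation to
#' 4-FBPA, pyridinium formation), cytosolic CBR1 reduction to reduced
#' haloperidol, and three recombinant-derived UGT glucuronidations scaled to
#' liver microsomes by ISEFs, plus a minor UGT1A4 N-glucuronidation.
#' Apparent Km values from binding-prone systems are corrected with the
#' incubation fraction unbound (0.35); the pyridinium Vmax is converted from
#' its per-pmol-CYP unit with a microsomal CYP content of 460 pmol/mg.
#'
#' @param correct_n_gluc_km Apply the incubation-binding correction also to
#'   the N-glucuronidation Km (default `FALSE`: that pathway's Km of
#'   64 µmol/L enters the model uncorrected).
#' @return A [compound()] object.
#' @examples
#' hal <- haloperidol()
#' hal$fraction_unbound       # 0.085
#' @export
haloperidol <- function(correct_n_gluc_km = FALSE) {
  fu_inc <- 0.35
  km_ngluc <- if (correct_n_gluc_km) correct_km(64, fu_inc) else 64
  compound(
    name = "haloperidol",
    molecular_weight = 376,
    effective_molecular_weight = 336.86,
    log_p = 3.66,
    pka = 8.65,
    water_solubility = 0.0045,
    fraction_unbound = 0.085,
    intestinal_permeability = 3.09e-4,
    gfr_fraction = 1,
    fu_incubation = fu_inc,
    pathways = list(
      metabolic_pathway("CYP3A4", "N-dealkylation to 4-FBPA", "HLM",
                        km_apparent = 62, km = correct_km(62, fu_inc),
                        vmax = 289, vmax_unit = "pmol/min/mg",
                        localization = "microsomal", product = "sink"),
      metabolic_pathway("CYP3A4", "oxidation to HPP+", "HLM",
                        km_apparent = 80, km = correct_km(80, fu_inc),
                        vmax = convert_vmax_per_pmol(0.53, 460),
                        vmax_unit = "pmol/min/mg",
                        localization = "microsomal", product = "sink"),
      metabolic_pathway("CBR1", "reduction to reduced haloperidol", "HLC",
                        km_apparent = 250, km = 88,
                        vmax = 1.30, vmax_unit = "nmol/min/mg",
                        localization = "cytosolic", enzyme_content = 75,
                        product = "reduced haloperidol"),
      metabolic_pathway("UGT1A4", "O-glucuronidation", "recombinant",
                        km_apparent = 64, km = correct_km(64, fu_inc),
                        vmax = 600, vmax_unit = "pmol/min/mg", isef = 0.16,
                        localization = "microsomal", enzyme_content = 33,
                        product = "sink"),
      metabolic_pathway("UGT1A9", "O-glucuronidation", "recombinant",
                        km_apparent = 174, km = 61,
                        vmax = 2300, vmax_unit = "pmol/min/mg", isef = 0.06,
                        localization = "microsomal", enzyme_content = 22.7,
                        product = "sink"),
      metabolic_pathway("UGT2B7", "O-glucuronidation", "recombinant",
                        km_apparent = 45, km = 16,
                        vmax = 1000, vmax_unit = "pmol/min/mg", isef = 0.05,
                        localization = "microsomal", enzyme_content = 69.4,
                        product = "sink"),
      metabolic_pathway("UGT1A4", "N-glucuronidation", "recombinant",
                        km_apparent = 64, km = km_ngluc,
                        vmax = 440, vmax_unit = "pmol/min/mg", isef = 0.16,
                        localization = "microsomal", enzyme_content = 33,
                        product = "sink")
    )
  )
}

#' The reduced haloperidol parameter set
#'
#' Parameterization of the carbonyl-reduction metabolite of haloperidol.
#' Its only enzymatic pathway is the CYP3A4 back-oxidation to haloperidol
#' (Km 46 µmol/L, Vmax 98 pmol/min/mg microsomal protein); remaining
#' elimination is represented as a linear additional hepatic plasma
#' clearance of 5 mL/min/kg.
#'
#' @return A [compound()] object.
#' @examples
#' reduced_haloperidol()$fraction_unbound  # 0.244
#' @export
reduced_haloperidol <- function() {
  compound(
    name = "reduced haloperidol",
    molecular_weight = 378,
    effective_molecular_weight = 339,
    log_p = 3.52,
    pka = 8.66,
    water_solubility = 0.0131,
    fraction_unbound = 0.244,
    intestinal_permeability = 2.08e-4,
    gfr_fraction = 1,
    pathways = list(
      metabolic_pathway("CYP3A4", "oxidation to haloperidol", "HLM",
                        km = 46, vmax = 98, vmax_unit = "pmol/min/mg",
                        localization = "microsomal", product = "haloperidol")
    ),
    additional_hepatic_clearance = 5
  )
}

#' Write a compound to a plain-text key-value configuration file
#'
#' The format is one `key = value` pair per line; pathway blocks are
#' introduced by `[pathway]` headers.  [read_compound()] restores the object
#' exactly (numbers are written with full precision).
#'
#' @param x A [compound()] object.
#' @param path File to write.
#' @return `path`, invisibly.
#' @export
write_compound <- function(x, path) {
  stopifnot(inherits(x, "compound"))
  num <- function(v) {
    if (is.na(v)) "NA" else format(v, digits = 17, scientific = TRUE)
  }
  lines <- c(
    paste("name =", x$name),
    paste("molecular_weight =", num(x$molecular_weight)),
    paste("effective_molecular_weight =", num(x$effective_molecular_weight)),
    paste("log_p =", num(x$log_p)),
    paste("pka =", num(x$pka)),
    paste("water_solubility =", num(x$water_solubility)),
    paste("fraction_unbound =", num(x$fraction_unbound)),
    paste("intestinal_permeability =", num(x$intestinal_permeability)),
    paste("gfr_fraction =", num(x$gfr_fraction)),
    paste("fu_incubation =", num(x$fu_incubation)),
    paste("additional_hepatic_clearance =",
          num(x$additional_hepatic_clearance))
  )
  for (p in x$pathways) {
    lines <- c(lines, "[pathway]",
               paste("enzyme =", p$enzyme),
               paste("reaction =", p$reaction),
               paste("system =", p$system),
               paste("km_apparent =", num(p$km_apparent)),
               paste("km =", num(p$km)),
               paste("vmax =", num(p$vmax)),
               paste("vmax_unit =", p$vmax_unit),
               paste("isef =", num(p$isef)),
               paste("localization =", p$localization),
               paste("enzyme_content =", num(p$enzyme_content)),
               paste("product =", p$product))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read a compound from a plain-text key-value configuration file
#'
#' @param path File written by [write_compound()].
#' @return A [compound()] object.
#' @export
read_compound <- function(path) {
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines)]
  blocks <- split(lines, cumsum(lines == "[pathway]"))
  parse_kv <- function(ls) {
    ls <- ls[ls != "[pathway]"]
    kv <- regmatches(ls, regexpr(" = ", ls), invert = TRUE)
    vals <- vapply(kv, `[`, character(1), 2)
    names(vals) <- vapply(kv, `[`, character(1), 1)
    as.list(vals)
  }
  n <- function(v) if (identical(v, "NA")) NA_real_ else as.numeric(v)
  head <- parse_kv(blocks[[1]])
  paths <- lapply(blocks[-1], function(b) {
    kv <- parse_kv(b)
    metabolic_pathway(kv$enzyme, kv$reaction, kv$system,
                      km_apparent = n(kv$km_apparent), km = n(kv$km),
                      vmax = n(kv$vmax), vmax_unit = kv$vmax_unit,
                      isef = n(kv$isef), localization = kv$localization,
                      enzyme_content = n(kv$enzyme_content),
                      product = kv$product)
  })
  compound(
    name = head$name,
    molecular_weight = n(head$molecular_weight),
    effective_molecular_weight = n(head$effective_molecular_weight),
    log_p = n(head$log_p), pka = n(head$pka),
    water_solubility = n(head$water_solubility),
    fraction_unbound = n(head$fraction_unbound),
    intestinal_permeability = n(head$intestinal_permeability),
    gfr_fraction = n(head$gfr_fraction),
    fu_incubation = n(head$fu_incubation),
    pathways = unname(paths),
    additional_hepatic_clearance = n(head$additional_hepatic_clearance)
  )
}
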