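#' Describe one dosing event
#'
#' @param route `"iv_bolus"`, `"iv_infusion"` or `"oral"`.
#' @param amount Dose amount, > 0.
#' @param unit `"mg"` (absolute) or `"mg/kg"` (scaled by the individual's
#'   body weight at simulation time).
#' @param start Start time (h).
#' @param infusion_duration Infusion length (h); required for
#'   `"iv_infusion"`.
#' @param compound Name of the dosed compound (default: the first compound
#'   of the model).
#' @return An object of class `"dose_regimen"`.
#' @export
dose_regimen <- function(route = c("iv_bolus", "iv_infusion", "oral"),
                         amount, unit = c("mg", "mg/kg"), start = 0,
                         infusion_duration = NULL, compound = NULL) {
  route <- match.arg(route)
  unit <- match.arg(unit)
  if (amount <= 0) stop("'amount' must be positive", call. = FALSE)
  if (route == "iv_infusion" &&
      (is.null(infusion_duration) || infusion_duration <= 0)) {
    stop("'infusion_duration' must be positive for iv_infusion",
         call. = FALSE)
  }
  structure(list(route = route, amount = amount, unit = unit, start = start,
                 infusion_duration = infusion_duration, compound = compound),
            class = "dose_regimen")
}

#' Default engine settings
#'
#' All tunable numerical and structural settings of the simulation engine
#' in one place.
#'
#' @param metabolic_scaling Global factor applied to every pathway's
#'   effective Vmax; the single in-vitro-to-in-vivo calibration degree of
#'   freedom (see [calibrate_metabolic_scaling()]).  The packaged default
#'   is the value calibrated against the mean intravenous clearance of the
#'   0.125 mg/kg study (11.1 mL/min/kg).
#' @param induction_fold CYP3A4 induction fold (>= 1); multiplies the
#'   effective Vmax of every CYP3A4 pathway of every compound.
#' @param blood_plasma Blood:plasma concentration ratio (see
#'   [blood_plasma_ratio()]).
#' @param area_multiplier Global multiplier on the effective absorptive
#'   surface-area-to-volume ratio of the gut wall (mucosal amplification).
#' @param dissolution `"ph_dependent"` (solid and dissolved lumen pools
#'   with Henderson-Hasselbalch solubility caps) or `"instant"`.
#' @param kp_override Optional single value or named per-organ vector
#'   forcing the tissue:plasma partition coefficients (verification hook;
#'   `NULL` uses the tissue-composition prediction).
#' @param rtol,atol Solver tolerances (stiff lsoda integrator).
#' @param output_resolution Output points per hour (default 12).
#' @param additional_cl_driver `"plasma"` (default) or `"intrinsic"`: how a
#'   compound's additional hepatic clearance is driven — by outflowing
#'   plasma concentration, or by unbound liver-water concentration.
#' @return A named list of settings.
#' @export
default_settings <- function(metabolic_scaling = hal_calibration$metabolic_scaling,
                             induction_fold = 1,
                             blood_plasma = 1,
                             area_multiplier = hal_calibration$area_multiplier,
                             dissolution = c("ph_dependent", "instant"),
                             kp_override = NULL,
                             rtol = 1e-8, atol = 1e-12,
                             output_resolution = 12,
                             additional_cl_driver = c("plasma", "intrinsic")) {
  list(metabolic_scaling = metabolic_scaling,
       induction_fold = induction_fold,
       blood_plasma = blood_plasma,
       area_multiplier = area_multiplier,
       dissolution = match.arg(dissolution),
       kp_override = kp_override,
       rtol = rtol, atol = atol,
       output_resolution = output_resolution,
       additional_cl_driver = match.arg(additional_cl_driver))
}

#' Assemble a whole-body PBPK model
#'
#' Binds compounds, a physiology (or population), a dosing schedule and
#' engine settings into a simulation-ready model object.  The model is a
#' perfusion-limited whole-body circuit: venous blood feeds the lung, the
#' lung feeds arterial blood, arterial blood perfuses every tissue, the gut
#' and spleen drain through the portal vein into the liver, and the liver
#' carries all enzymatic elimination.  Orally dosed drug transits a
#' compartmental gut lumen (stomach, seven small-intestinal segments,
#' colon) and is absorbed into the portal inflow, giving a hepatic
#' first pass.
#'
#' @param compounds A [compound()] or list of 1-2 compounds; the parent
#'   must come first.  Pathway products must name a listed compound or
#'   `"sink"`.
#' @param physiology A [reference_individual()] or a population from
#'   [sample_population()].
#' @param dosing A [dose_regimen()] or list of them.
#' @param duration Simulated time span (h).
#' @param settings See [default_settings()].
#' @return An object of class `"pbpk_model"`.
#' @examples
#' mod <- pbpk_model(list(haloperidol(), reduced_haloperidol()),
#'                   reference_individual(),
#'                   dose_regimen("iv_bolus", 5), duration = 48)
#' @export
pbpk_model <- function(compounds, physiology,
                       dosing, duration = 96,
                       settings = default_settings()) {
  if (inherits(compounds, "compound")) compounds <- list(compounds)
  stopifnot(length(compounds) >= 1, length(compounds) <= 2,
            all(vapply(compounds, inherits, logical(1), "compound")),
            duration > 0)
  if (inherits(dosing, "dose_regimen")) dosing <- list(dosing)
  stopifnot(all(vapply(dosing, inherits, logical(1), "dose_regimen")))
  cnames <- vapply(compounds, `[[`, character(1), "name")
  if (anyDuplicated(cnames)) stop("duplicate compound names", call. = FALSE)
  for (cp in compounds) {
    for (p in cp$pathways) {
      if (p$product != "sink" && !(p$product %in% cnames)) {
        stop("pathway product '", p$product,
             "' does not resolve to a model compound or 'sink'",
             call. = FALSE)
      }
    }
  }
  for (d in dosing) {
    if (is.null(d$compound)) d$compound <- cnames[1]
    if (!(d$compound %in% cnames)) {
      stop("dose targets unknown compound '", d$compound, "'",
           call. = FALSE)
    }
  }
  if (settings$induction_fold < 1) {
    stop("'induction_fold' must be >= 1", call. = FALSE)
  }
  if (settings$induction_fold > 1) {
    has3a4 <- any(vapply(compounds, function(cp) {
      any(vapply(cp$pathways, function(p) p$enzyme == "CYP3A4", logical(1)))
    }, logical(1)))
    if (!has3a4) {
      stop("induction requested but no CYP3A4 pathway in the model",
           call. = FALSE)
    }
  }
  structure(list(compounds = compounds, physiology = physiology,
                 dosing = dosing, duration = duration, settings = settings),
            class = "pbpk_model")
}

#' Apply CYP3A4 induction to a model
#'
#' Returns the model with the effective Vmax of every CYP3A4 pathway (of
#' every compound) multiplied by `fold`; all other pathways are untouched.
#' A static induction fold represents steady-state co-treatment with an
#' inducer such as rifampicin 600 mg/day.
#'
#' @param model A [pbpk_model()].
#' @param fold Induction fold, >= 1; `fold = 1` leaves the model unchanged.
#' @return The modified model.
#' @export
apply_induction <- function(model, fold) {
  stopifnot(inherits(model, "pbpk_model"))
  if (fold < 1) stop("'fold' must be >= 1", call. = FALSE)
  has3a4 <- any(vapply(model$compounds, function(cp) {
    any(vapply(cp$pathways, function(p) p$enzyme == "CYP3A4", logical(1)))
  }, logical(1)))
  if (!has3a4) stop("model has no CYP3A4 pathway", call. = FALSE)
  model$settings$induction_fold <- fold
  model
}

#' @export
print.pbpk_model <- function(x, ...) {
  cat("<pbpk_model>\n")
  cat("  compounds:", paste(vapply(x$compounds, `[[`, character(1), "name"),
                            collapse = " -> "), "\n")
  pop <- inherits(x$physiology, "population")
  cat("  physiology:",
      if (pop) sprintf("population of %d", length(x$physiology))
      else sprintf("%s %g y, %g kg", x$physiology$sex, x$physiology$age,
                   x$physiology$body_weight), "\n")
  for (d in x$dosing) {
    cat(sprintf("  dose: %s %g %s at %g h\n", d$route, d$amount, d$unit,
                d$start))
  }
  cat(sprintf("  duration %g h; metabolic scaling %.4g; induction fold %.4g\n",
              x$duration, x$settings$metabolic_scaling,
              x$settings$induction_fold))
  invisible(x)
}

#' @importFrom stats coef
#' @export
coef.pbpk_model <- function(object, ...) {
  phys <- if (inherits(object$physiology, "population")) {
    object$physiology[[1]]
  } else object$physiology
  out <- list()
  for (cp in object$compounds) {
    kp <- effective_kp(cp, phys, object$settings)
    ve <- effective_vmax(cp, phys, object$settings)
    out[[cp$name]] <- list(
      kp = kp,
      blood_plasma = blood_plasma_ratio(cp, object$settings$blood_plasma),
      vmax_eff_umol_h = ve,
      km_umol_L = vapply(cp$pathways, `[[`, numeric(1), "km"),
      renal_cl_L_h = cp$gfr_fraction * phys$gfr * 60 / 1000 *
        cp$fraction_unbound)
  }
  out
}

#' @export
summary.pbpk_model <- function(object, ...) {
  print(object)
  cf <- coef(object)
  for (nm in names(cf)) {
    cat("\n", nm, " tissue:plasma partition coefficients:\n", sep = "")
    print(round(cf[[nm]]$kp, 2))
  }
  invisible(cf)
}

# effective Kp vector for one compound (settings override hook)
effective_kp <- function(compound, physiology, settings) {
  if (!is.null(settings$kp_override)) {
    org <- physiology$tissue_composition$organ
    ov <- settings$kp_override
    if (length(ov) == 1 && is.null(names(ov))) {
      return(stats::setNames(rep(ov, length(org)), org))
    }
    kp <- partition_coefficients(compound, physiology,
                                 blood_plasma = settings$blood_plasma)
    kp[names(ov)] <- ov
    return(kp)
  }
  partition_coefficients(compound, physiology,
                         blood_plasma = settings$blood_plasma)
}

# effective Vmax per pathway in µmol/h for the whole liver, including
# protein scaling, activity multipliers, global metabolic scaling and
# CYP3A4 induction
effective_vmax <- function(compound, physiology, settings) {
  vapply(compound$pathways, function(p) {
    protein <- switch(p$localization,
                      microsomal = physiology$mppgl,
                      cytosolic = physiology$cppgl)
    act <- physiology$pathway_activity[[p$enzyme]]
    if (is.null(act) || is.na(act)) act <- 1
    ind <- if (p$enzyme == "CYP3A4") settings$induction_fold else 1
    p$vmax_umol_min_mg * protein * physiology$liver_weight * 60 *
      act * settings$metabolic_scaling * ind
  }, numeric(1))
}
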