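#' Frozen calibration constants
#'
#' The three calibrated constants of the packaged model, each the result of
#' a single documented one-dimensional calibration (see the corresponding
#' `calibrate_*()` function):
#' \describe{
#'   \item{metabolic_scaling}{Global in-vitro-to-in-vivo factor on every
#'     pathway's effective Vmax, calibrated so that the simulated mean
#'     intravenous clearance of the 0.125 mg/kg study equals the observed
#'     11.1 mL/min/kg.}
#'   \item{tb_protein_scale}{Relative plasma binding-protein level of the
#'     tuberculosis population, calibrated so that the 5 mg IV control-arm
#'     AUC matches the reported prediction of 174 ng·h/mL (tuberculosis
#'     raises alpha-1-acid glycoprotein, lowering the free fraction).}
#'   \item{rifampicin_fold}{Static CYP3A4 induction fold of steady-state
#'     rifampicin 600 mg/day, calibrated so that the induced/control AUC
#'     ratio in the tuberculosis scenario equals 0.60.}
#' }
#' The values stored here were produced by running the calibrations below
#' and are re-derivable at any time.
#'
#' @format A named list of four numbers.
#' @export
hal_calibration <- list(
  metabolic_scaling = 2.398662,
  area_multiplier = 9.555313,
  tb_protein_scale = 1.752660,
  rifampicin_fold = 3.282741
)

#' Calibrate the absorptive surface-area multiplier
#'
#' Finds the global mucosal amplification multiplier of the gut-wall
#' absorption model such that the simulated peak concentration of the
#' calibration scenario (0.503 mg/kg oral in healthy adults) equals the
#' observed Cmax.  This is the absorption-phase parameter-identification
#' step: the multiplier collapses the unobservable product of effective
#' absorptive area and segmental fluid geometry into one degree of freedom
#' fitted to oral data, after the elimination side has been fixed from
#' intravenous data.
#'
#' @param target_cmax Target peak concentration (ng/mL), default 37.4.
#' @param scenario_id Calibration scenario, default
#'   `"oral_0.503mgkg_healthy_40"`.
#' @param interval Search interval for the multiplier.
#' @param settings Base engine settings (with the calibrated metabolic
#'   scaling).
#' @param tol Root tolerance on Cmax (ng/mL).
#' @return The calibrated area multiplier.
#' @export
calibrate_absorption <- function(target_cmax = 37.4,
                                 scenario_id = "oral_0.503mgkg_healthy_40",
                                 interval = c(2, 80),
                                 settings = default_settings(),
                                 tol = 1e-2) {
  f <- function(m) {
    st <- settings; st$area_multiplier <- m
    run_scenario(scenario_id, settings = st)$nca$cmax - target_cmax
  }
  stats::uniroot(f, interval, tol = tol)$root
}

#' Calibrate the global metabolic scaling factor
#'
#' Finds the single global multiplier on all effective Vmax values such
#' that the simulated clearance of the calibration scenario (0.125 mg/kg
#' IV in the healthy adult study) equals a target clearance.  This is the
#' one in-vitro-to-in-vivo degree of freedom of the model; it stands in
#' for hepatic enzyme-expression data that in vitro assays do not fix.
#'
#' @param target_cl Target clearance (mL/min/kg), default 11.1.
#' @param scenario_id Calibration scenario, default
#'   `"iv_0.125mgkg_healthy_40"`.
#' @param interval Search interval for the factor.
#' @param settings Base engine settings.
#' @param tol Root tolerance on the clearance (mL/min/kg).
#' @return The calibrated scaling factor.
#' @export
calibrate_metabolic_scaling <- function(target_cl = 11.1,
                                        scenario_id = "iv_0.125mgkg_healthy_40",
                                        interval = c(0.5, 20),
                                        settings = default_settings(),
                                        tol = 1e-3) {
  f <- function(s) {
    st <- settings; st$metabolic_scaling <- s
    run_scenario(scenario_id, settings = st)$nca$cl - target_cl
  }
  stats::uniroot(f, interval, tol = tol)$root
}

#' Calibrate the tuberculosis plasma-protein scale
#'
#' Finds the relative binding-protein level of the tuberculosis population
#' such that the simulated 5 mg IV control-arm AUC matches a target.
#'
#' @param target_auc Target AUC (ng·h/mL), default 174.
#' @param interval Search interval for the scale.
#' @param settings Engine settings (with the calibrated metabolic scaling).
#' @param tol Root tolerance on the AUC (ng·h/mL).
#' @return The calibrated protein scale.
#' @export
calibrate_protein_scale <- function(target_auc = 174,
                                    interval = c(0.5, 5),
                                    settings = default_settings(),
                                    tol = 1e-3) {
  f <- function(sc) {
    m <- scenario_model("iv_5mg_tb_control_45", settings,
                        tb_protein_scale = sc)
    sim <- stats::simulate(m)
    tb_nca(sim)$auc_inf - target_auc
  }
  stats::uniroot(f, interval, tol = tol)$root
}

# NCA of the tuberculosis 5 mg IV scenario on its sampling schedule.
tb_nca <- function(sim, first = 1) {
  grid <- .sampling_grid(first, "iv")
  conc <- stats::approx(sim$times, sim$conc[["haloperidol"]], xout = grid)$y
  nca(grid, conc, dose = 5, body_weight = 70)
}

#' Calibrate the rifampicin CYP3A4 induction fold
#'
#' Scalar root-find on the static induction fold such that the simulated
#' induced/control AUC ratio of the 5 mg IV tuberculosis scenario equals
#' the target.
#'
#' @param target_auc_ratio Target induced/control AUC ratio in (0, 1);
#'   default 0.60.
#' @param interval Search interval for the fold.
#' @param settings Engine settings (with the calibrated metabolic scaling
#'   and protein scale).
#' @param tol Root tolerance on the ratio.
#' @return The calibrated induction fold.
#' @export
calibrate_induction <- function(target_auc_ratio = 0.60,
                                interval = c(1, 50),
                                settings = default_settings(),
                                tol = 1e-3) {
  if (target_auc_ratio <= 0 || target_auc_ratio > 1) {
    stop("'target_auc_ratio' must be in (0, 1]", call. = FALSE)
  }
  if (target_auc_ratio == 1) return(1)
  control <- tb_nca(stats::simulate(
    scenario_model("iv_5mg_tb_control_45", settings)))$auc_inf
  f <- function(fold) {
    st <- settings; st$induction_fold <- fold
    m <- scenario_model("iv_5mg_tb_control_45", st)
    m$settings$induction_fold <- fold
    tb_nca(stats::simulate(m))$auc_inf / control - target_auc_ratio
  }
  lo <- f(interval[1]); hi <- f(interval[2])
  if (lo * hi > 0) {
    stop("target AUC ratio not bracketed by fold interval [",
         interval[1], ", ", interval[2], "]", call. = FALSE)
  }
  stats::uniroot(f, interval, f.lower = lo, f.upper = hi, tol = tol)$root
}

#' Scan dose increases against the induction-mediated exposure loss
#'
#' Simulates the 5 mg IV tuberculosis control arm (no inducer, base dose)
#' and induced arms with the dose increased by each percentage, and
#' reports the mean AUC per arm together with the arm closest to the
#' control exposure.
#'
#' @param increases Dose increases in percent (default 50, 75, 100).
#' @param settings Engine settings.
#' @param induction_fold Induction fold of the induced arms (default: the
#'   calibrated rifampicin fold).
#' @param base_dose Base dose (mg), default 5.
#' @return A data.frame (arm, dose_mg, auc_inf, auc_over_control) with the
#'   attribute `"closest"` naming the arm nearest to control.
#' @export
dose_adjustment_scan <- function(increases = c(50, 75, 100),
                                 settings = default_settings(),
                                 induction_fold = hal_calibration$rifampicin_fold,
                                 base_dose = 5) {
  sim_arm <- function(dose, fold) {
    st <- settings; st$induction_fold <- fold
    m <- scenario_model("iv_5mg_tb_control_45", st)
    m$dosing <- list(dose_regimen("iv_bolus", dose, "mg",
                                  compound = "haloperidol"))
    tb_nca(stats::simulate(m))$auc_inf
  }
  control <- sim_arm(base_dose, 1)
  arms <- data.frame(
    arm = c("control", paste0("+", increases, "%")),
    dose_mg = c(base_dose, base_dose * (1 + increases / 100)),
    fold = c(1, rep(induction_fold, length(increases))))
  arms$auc_inf <- c(control, vapply(seq_along(increases), function(i) {
    sim_arm(arms$dose_mg[i + 1], induction_fold)
  }, numeric(1)))
  arms$auc_over_control <- arms$auc_inf / control
  induced <- arms[-1, ]
  attr(arms, "closest") <-
    induced$arm[which.min(abs(induced$auc_inf - control))]
  arms
}
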