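# Simulation conditions for each clinical study scenario: the mean
# demographic of the study group, and the sparse sampling schedule on which
# predicted PK parameters are computed.  Where a study reports only a
# weight range the midpoint is used; where demographics are absent the
# reference adult stands in.  The time of the first post-dose sample is
# reconstructed per study from the reported peak concentrations (dose and
# observed Cmax imply the effective initial distribution volume, hence how
# early the study sampled); later samples follow a common sparse grid.
.scenario_sim <- list(
  "iv_0.125mgkg_healthy_40"  = list(bw = 70.5, age = 30, first = 2),
  "iv_0.125mgkg_healthy_41"  = list(bw = 74,   age = 28, first = 2),
  "iv_0.125mgkg_psych_42"    = list(bw = 63.3, age = 34, first = 1),
  "iv_10mg_healthy_43"       = list(bw = 70,   age = 30, first = 2),
  "iv_5mg_psych_44"          = list(bw = 74,   age = 55, first = 0.0833),
  "iv_5mg_tb_control_45"     = list(bw = 70,   age = 45, first = 1, tb = TRUE),
  "iv_5mg_tb_rifampicin_45"  = list(bw = 70,   age = 45, first = 1, tb = TRUE,
                                    induced = TRUE),
  "iv_3.5mg_psych_46"        = list(bw = 67,   age = 31, first = 1.5),
  "iv_2.5mg_healthy_47"      = list(bw = 72.5, age = 30, first = 0.5),
  "oral_0.503mgkg_healthy_40" = list(bw = 70.8, age = 28, first = 0.5),
  "oral_0.5mgkg_healthy_41"   = list(bw = 74,   age = 28, first = 0.5),
  "oral_0.5mgkg_psych_42"     = list(bw = 63.3, age = 34, first = 0.5),
  "oral_10mg_psych_48"        = list(bw = 54.5, age = 44, first = 0.5),
  "oral_5mg_healthy_49"       = list(bw = 71.5, age = 34, first = 0.5),
  "oral_2mg_psych_46"         = list(bw = 67,   age = 32, first = 0.5),
  "rhal_after_iv_0.125mgkg_42"  = list(bw = 63.3, age = 34, first = 1,
                                       metabolite = TRUE,
                                       base = "iv_0.125mgkg_psych_42"),
  "rhal_after_oral_0.5mgkg_42"  = list(bw = 63.3, age = 34, first = 0.5,
                                       metabolite = TRUE,
                                       base = "oral_0.5mgkg_psych_42"),
  "rhal_oral_10mg_48"           = list(bw = 54.5, age = 44, first = 0.5,
                                       rhal_parent = TRUE)
)

.sampling_grid <- function(first, route) {
  base <- c(0.5, 1, 1.5, 2, 3, 4, 6, 8, 12, 24, 36, 48, 72, 96)
  sort(unique(c(first, base[base >= first])))
}

#' List the packaged simulation scenarios
#'
#' One scenario per clinical study row of the packaged study catalog,
#' joined with the simulation conditions (mean demographic, sampling
#' schedule) the package uses for it.
#'
#' @return A data.frame: scenario id, compound, route, dose, simulated body
#'   weight and age, first sampling time.
#' @export
scenario_catalog <- function() {
  studies <- load_pk_tables()$studies
  sim <- .scenario_sim[studies$scenario_id]
  data.frame(
    scenario_id = studies$scenario_id,
    compound = studies$compound,
    route = studies$route,
    dose = studies$dose,
    dose_unit = studies$dose_unit,
    population = studies$population,
    sim_body_weight = vapply(sim, `[[`, numeric(1), "bw"),
    sim_age = vapply(sim, `[[`, numeric(1), "age"),
    first_sample_h = vapply(sim, `[[`, numeric(1), "first"),
    stringsAsFactors = FALSE
  )
}

# Build the pbpk_model for a scenario id.
scenario_model <- function(scenario_id, settings = default_settings(),
                           tb_protein_scale = hal_calibration$tb_protein_scale,
                           induction_fold = hal_calibration$rifampicin_fold,
                           with_metabolite = NULL, duration = 96) {
  studies <- load_pk_tables()$studies
  row <- studies[studies$scenario_id == scenario_id, ]
  if (nrow(row) != 1) {
    stop("unknown scenario '", scenario_id, "'", call. = FALSE)
  }
  sc <- .scenario_sim[[scenario_id]]
  rhal_parent <- isTRUE(sc$rhal_parent)
  metabolite <- isTRUE(sc$metabolite)
  if (is.null(with_metabolite)) with_metabolite <- metabolite
  phys <- reference_individual(
    age = sc$age, body_weight = sc$bw,
    plasma_protein_scale = if (isTRUE(sc$tb)) tb_protein_scale else 1,
    override = TRUE)
  if (isTRUE(sc$induced)) settings$induction_fold <- induction_fold
  # the model is always the coupled parent-metabolite pair; the dosed
  # compound comes first
  compounds <- if (rhal_parent) {
    list(reduced_haloperidol(), haloperidol())
  } else {
    list(haloperidol(), reduced_haloperidol())
  }
  route <- if (row$route == "iv") "iv_bolus" else "oral"
  unit <- if (row$dose_unit == "mg/kg") "mg/kg" else "mg"
  dosed <- if (rhal_parent) "reduced haloperidol" else "haloperidol"
  pbpk_model(compounds, phys,
             dose_regimen(route, row$dose, unit, compound = dosed),
             duration = duration, settings = settings)
}

#' Run one packaged scenario end to end
#'
#' Builds the scenario's model, simulates the mean individual (or a virtual
#' population), samples the simulated curve on the scenario's clinical
#' sampling schedule, runs [nca()], and, where the scenario appears in the
#' packaged qualification tables, evaluates predicted against observed
#' values.
#'
#' @param scenario_id One id from [scenario_catalog()].
#' @param settings Engine settings, see [default_settings()].
#' @param population `FALSE` (mean individual, default) or `TRUE`.
#' @param n,seed Population size and seed when `population = TRUE`.
#' @param duration Simulated span (h), default 96.
#' @return A list: `scenario_id`, `profile` (data.frame of the sampled
#'   schedule), `sim` (the full simulation object), `nca`, `dose_mg`,
#'   `body_weight`, and `evaluation` (data.frame or `NULL`).
#' @export
run_scenario <- function(scenario_id, settings = default_settings(),
                         population = FALSE, n = 100, seed = 1,
                         duration = 96) {
  sc <- .scenario_sim[[scenario_id]]
  if (is.null(sc)) stop("unknown scenario '", scenario_id, "'", call. = FALSE)
  model <- scenario_model(scenario_id, settings, duration = duration)
  studies <- load_pk_tables()$studies
  row <- studies[studies$scenario_id == scenario_id, ]
  if (population) {
    wr <- c(0.9, 1.1) * sc$bw
    pop <- sample_population(n, weight_range = wr,
                             age_range = c(max(18, sc$age - 10), sc$age + 10),
                             seed = seed)
    if (isTRUE(sc$tb)) {
      for (i in seq_along(pop)) {
        pop[[i]]$plasma_protein_scale <- model$physiology$plasma_protein_scale
      }
    }
    model$physiology <- pop
  }
  sim <- stats::simulate(model)
  grid <- .sampling_grid(sc$first, row$route)
  target <- if (isTRUE(sc$metabolite) || isTRUE(sc$rhal_parent)) {
    if (isTRUE(sc$rhal_parent)) "reduced haloperidol" else "reduced haloperidol"
  } else "haloperidol"
  curve <- if (population) sim$bands[[target]]$mean else sim$conc[[target]]
  times <- if (population) sim$bands[[target]]$time else sim$times
  sampled <- stats::approx(times, curve, xout = grid)$y
  dose_mg <- if (row$dose_unit == "mg/kg") row$dose * sc$bw else row$dose
  res <- nca(grid, sampled, dose = dose_mg, body_weight = sc$bw)
  evaluation <- scenario_evaluation(scenario_id, res)
  list(scenario_id = scenario_id,
       profile = data.frame(time = grid, conc = sampled),
       sim = sim, nca = res, dose_mg = dose_mg, body_weight = sc$bw,
       evaluation = evaluation)
}

# Compare one scenario's NCA against the packaged observed values.
scenario_evaluation <- function(scenario_id, nca_res) {
  tabs <- load_pk_tables()
  obs <- rbind(tabs$iv, tabs$oral)
  obs <- obs[obs$scenario_id == scenario_id, ]
  if (!nrow(obs)) return(NULL)
  pred <- c(auc_inf = nca_res$auc_inf, cmax = nca_res$cmax, cl = nca_res$cl)
  obs$model_predicted <- pred[obs$parameter]
  obs$model_ratio <- pred_obs_ratio(obs$model_predicted, obs$observed)
  obs$model_pe <- prediction_error(obs$model_predicted, obs$observed)
  obs$fold_error <- pmax(obs$model_ratio, 1 / obs$model_ratio)
  obs[, c("scenario_id", "parameter", "model_predicted", "observed",
          "model_ratio", "model_pe", "fold_error")]
}

#' Evaluate the model across all qualification scenarios
#'
#' Runs every haloperidol scenario that appears in the packaged
#' qualification tables, collects predicted-vs-observed records, and
#' summarises MFE, RMSE and the two-fold verdict per route and parameter.
#'
#' @param settings Engine settings.
#' @param scenarios Scenario ids (default: all scenarios present in the
#'   qualification tables).
#' @return A list: `records` (one row per scenario x parameter), `summary`
#'   (MFE/RMSE per route and parameter), `two_fold` (verdict over all
#'   records).
#' @export
evaluate_scenarios <- function(settings = default_settings(),
                               scenarios = NULL) {
  tabs <- load_pk_tables()
  if (is.null(scenarios)) {
    scenarios <- unique(c(tabs$iv$scenario_id, tabs$oral$scenario_id))
  }
  records <- do.call(rbind, lapply(scenarios, function(id) {
    r <- run_scenario(id, settings = settings)
    ev <- r$evaluation
    ev$route <- if (grepl("^iv", id)) "iv" else "oral"
    ev
  }))
  summary <- do.call(rbind, lapply(split(records,
                                         list(records$route,
                                              records$parameter)),
                                   function(g) {
    data.frame(route = g$route[1], parameter = g$parameter[1],
               n = nrow(g),
               mfe = mfe(g$model_predicted, g$observed),
               rmse = rmse(g$model_predicted, g$observed))
  }))
  rownames(summary) <- NULL
  tf <- two_fold_check(records$model_predicted, records$observed)
  list(records = records, summary = summary, two_fold = tf)
}
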