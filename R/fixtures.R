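#' Load the packaged study catalog and qualification tables
#'
#' Returns the machine-readable clinical-study catalog (dose, route, group
#' size, demographics per study), the predicted/observed PK aggregates for
#' the intravenous and oral qualification sets (with the flag marking which
#' observed values were themselves NCA-derived), the interaction-arm
#' comparison, and the printed MFE/RMSE footers.  These tables ship as CSV
#' package data so that every evaluation is reproducible offline.
#'
#' @return A list of data.frames: `studies`, `iv`, `oral`, `ddi`, `footers`.
#' @examples
#' tabs <- load_pk_tables()
#' subset(tabs$iv, parameter == "auc_inf")
#' @export
load_pk_tables <- function() {
  f <- function(name) {
    utils::read.csv(system.file("extdata", name, package = "halopbpk"),
                    stringsAsFactors = FALSE)
  }
  list(studies = f("table1_studies.csv"),
       iv = f("table4_iv.csv"),
       oral = f("table5_oral.csv"),
       ddi = f("table6_ddi.csv"),
       footers = f("table_footers.csv"))
}

#' Generate a synthetic observed concentration-time profile
#'
#' Emulates sparse clinical sampling of a known disposition curve with
#' multiplicative log-normal residual error: observed concentrations are
#' \eqn{C(t_j) \exp(\epsilon_j)} with \eqn{\epsilon_j \sim N(0, \sigma^2)},
#' \eqn{\sigma = \sqrt{\log(1 + CV^2)}}, so that the multiplicative error
#' has coefficient of variation `cv`.  Values below the lower limit of
#' quantification are dropped.
#'
#' @param times Sampling times (h), increasing.
#' @param true_conc True concentrations at `times` (ng/mL), or `NULL` to
#'   evaluate a bi-exponential `coef` instead.
#' @param coef Optional list `list(C = c(...), lambda = c(...))` of
#'   bi-/multi-exponential coefficients (ng/mL, 1/h): the true curve is
#'   \eqn{\sum_i C_i e^{-\lambda_i t}}.
#' @param cv Residual coefficient of variation (fraction, >= 0).
#' @param lloq Lower limit of quantification (ng/mL); samples below are
#'   removed.
#' @param seed Integer seed (reproducible draws).
#' @return A data.frame `time`, `conc`.
#' @examples
#' synthetic_profile(c(1, 2, 4, 8, 24),
#'                   coef = list(C = c(60, 40), lambda = c(1.2, 0.06)),
#'                   cv = 0.2, seed = 7)
#' @export
synthetic_profile <- function(times, true_conc = NULL, coef = NULL,
                              cv = 0, lloq = 0, seed = NULL) {
  if (is.null(true_conc)) {
    if (is.null(coef)) stop("supply 'true_conc' or 'coef'", call. = FALSE)
    if (any(coef$lambda <= 0)) stop("lambda must be positive", call. = FALSE)
    true_conc <- multiexp(times, coef)
  }
  stopifnot(length(times) == length(true_conc), cv >= 0)
  if (any(diff(times) <= 0)) stop("'times' must be increasing", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  sdlog <- sqrt(log(1 + cv^2))
  conc <- true_conc * if (cv > 0) exp(stats::rnorm(length(times), 0, sdlog))
  else 1
  keep <- conc >= lloq
  data.frame(time = times[keep], conc = conc[keep])
}

multiexp <- function(times, coef) {
  rowSums(vapply(seq_along(coef$C),
                 function(i) coef$C[i] * exp(-coef$lambda[i] * times),
                 numeric(length(times))))
}

#' Bias and precision of NCA estimates under sampling noise
#'
#' Repeatedly generates noisy observations of a known multi-exponential
#' curve, runs [nca()] on each replicate, and summarises the relative bias
#' and the coefficient of variation of the AUC and half-life estimates
#' against their analytic truths (\eqn{AUC = \sum_i C_i/\lambda_i};
#' terminal \eqn{t_{1/2} = \log 2 / \min_i \lambda_i}).
#'
#' @param coef Multi-exponential coefficients as in [synthetic_profile()].
#' @param times Sampling schedule (h).
#' @param cv Residual CV of the observations.
#' @param replicates Number of replicates.
#' @param seed Integer seed.
#' @param lambda_z_points Terminal points used by [nca()].
#' @return A list with analytic truths (`auc_true`, `t_half_true`) and a
#'   data.frame `summary` (parameter, relative bias, CV of the estimates).
#' @export
nca_recovery_experiment <- function(coef, times, cv, replicates, seed,
                                    lambda_z_points = 4) {
  auc_true <- sum(coef$C / coef$lambda)
  t_half_true <- log(2) / min(coef$lambda)
  set.seed(seed)
  est <- t(vapply(seq_len(replicates), function(i) {
    obs <- synthetic_profile(times, coef = coef, cv = cv)
    r <- nca(obs$time, obs$conc, lambda_z_points = lambda_z_points)
    c(auc = r$auc_inf, t_half = r$t_half)
  }, numeric(2)))
  summarise <- function(x, truth) {
    c(bias = mean(x) / truth - 1, cv = stats::sd(x) / mean(x))
  }
  a <- summarise(est[, "auc"], auc_true)
  h <- summarise(est[, "t_half"], t_half_true)
  list(auc_true = auc_true, t_half_true = t_half_true,
       summary = data.frame(parameter = c("auc_inf", "t_half"),
                            rel_bias = c(a["bias"], h["bias"]),
                            cv = c(a["cv"], h["cv"]),
                            row.names = NULL))
}
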