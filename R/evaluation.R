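#' Predicted-to-observed ratio
#'
#' @param predicted,observed PK parameter values; `observed` must be > 0.
#' @return `predicted / observed`.
#' @examples
#' pred_obs_ratio(168, 202)  # 0.83
#' @export
pred_obs_ratio <- function(predicted, observed) {
  if (any(observed <= 0)) stop("'observed' must be positive", call. = FALSE)
  predicted / observed
}

#' Prediction error (%)
#'
#' Relative deviation of a predicted PK parameter from its observed value,
#' in percent.  By default the magnitude is returned (qualification tables
#' print non-negative errors); `signed = TRUE` keeps the sign.
#'
#' @param predicted,observed PK parameter values; `observed` must be > 0.
#' @param signed Keep the sign of the deviation (default `FALSE`).
#' @return Prediction error in percent.
#' @examples
#' prediction_error(193, 202)  # 4.46
#' @export
prediction_error <- function(predicted, observed, signed = FALSE) {
  if (any(observed <= 0)) stop("'observed' must be positive", call. = FALSE)
  pe <- (predicted - observed) / observed * 100
  if (signed) pe else abs(pe)
}

#' Mean fold error of a set of predicted/observed pairs
#'
#' In the default `"mean-of-ratios"` mode the MFE is the arithmetic mean of
#' the per-record predicted/observed ratios, which is the form that
#' reproduces the printed qualification footers.  `"ratio-of-means"`
#' computes the quotient of the mean predicted and mean observed values
#' instead; both agree when all observed values are equal.
#'
#' @param predicted,observed Numeric vectors of equal length; `observed`
#'   values must be > 0.
#' @param mode `"mean-of-ratios"` (default) or `"ratio-of-means"`.
#' @return The mean fold error (dimensionless).
#' @export
mfe <- function(predicted, observed,
                mode = c("mean-of-ratios", "ratio-of-means")) {
  mode <- match.arg(mode)
  if (!length(predicted)) stop("empty input", call. = FALSE)
  stopifnot(length(predicted) == length(observed))
  if (any(observed <= 0)) stop("'observed' must be positive", call. = FALSE)
  switch(mode,
         "mean-of-ratios" = mean(predicted / observed),
         "ratio-of-means" = mean(predicted) / mean(observed))
}

#' Root-mean-square error of predicted vs observed values
#'
#' @param predicted,observed Numeric vectors of equal length.
#' @return RMSE in the units of the parameter.
#' @export
rmse <- function(predicted, observed) {
  if (!length(predicted)) stop("empty input", call. = FALSE)
  stopifnot(length(predicted) == length(observed))
  sqrt(mean((observed - predicted)^2))
}

#' Exposure-change ratios of an interaction arm over its control
#'
#' The three induced/control quotients used to summarise a drug-drug
#' interaction: AUC extrapolated to infinity, the concentration at the end
#' of the simulation, and the terminal half-life.
#'
#' @param induced,control Lists (or [nca()] objects) carrying `auc_inf`,
#'   `c_tend` and `t_half`.
#' @return Named list `auc_ratio`, `c_tend_ratio`, `t_half_ratio`.
#' @examples
#' interaction_ratios(list(auc_inf = 103.85, c_tend = 1, t_half = 4.76),
#'                    list(auc_inf = 174,    c_tend = 2, t_half = 11.5))
#' @export
interaction_ratios <- function(induced, control) {
  need <- c("auc_inf", "c_tend", "t_half")
  for (nm in need) {
    if (is.null(induced[[nm]]) || is.null(control[[nm]])) {
      stop("missing parameter '", nm, "'", call. = FALSE)
    }
  }
  list(auc_ratio = induced$auc_inf / control$auc_inf,
       c_tend_ratio = induced$c_tend / control$c_tend,
       t_half_ratio = induced$t_half / control$t_half)
}

#' Two-fold acceptance check
#'
#' A prediction passes when its fold error, `max(ratio, 1/ratio)` of the
#' predicted/observed ratio, does not exceed 2.
#'
#' @param predicted,observed Numeric vectors of equal length, positive.
#' @return A list: `pass` (logical, all records within two-fold),
#'   `max_fold_error`, and the per-record `fold_error` vector.
#' @export
two_fold_check <- function(predicted, observed) {
  if (!length(predicted)) stop("empty input", call. = FALSE)
  r <- pred_obs_ratio(predicted, observed)
  fe <- pmax(r, 1 / r)
  list(pass = all(fe <= 2), max_fold_error = max(fe), fold_error = fe)
}

#' Pointwise percentile bands of a set of simulated profiles
#'
#' Computes the visual-predictive-check band: for each time point of a
#' common grid, the requested percentiles across individual profiles.  When
#' observed points are supplied, the fraction falling inside the band
#' (closed interval, at matched times) is reported.
#'
#' @param times Common time grid (h).
#' @param profiles Matrix of concentrations, one row per individual,
#'   `length(times)` columns; at least 10 rows.
#' @param percentiles Two probabilities in percent (default `c(5, 95)`).
#' @param observed Optional data.frame with columns `time` and `conc`;
#'   each observed time must be on the grid.
#' @return A list: `band` (data.frame time/lower/upper/median) and
#'   `coverage` (fraction of observed points inside the band, or `NA`).
#' @export
vpc_bands <- function(times, profiles, percentiles = c(5, 95),
                      observed = NULL) {
  profiles <- as.matrix(profiles)
  if (ncol(profiles) != length(times)) {
    stop("profiles must have one column per time point", call. = FALSE)
  }
  if (nrow(profiles) < 10) stop("need at least 10 profiles", call. = FALSE)
  p <- sort(percentiles) / 100
  qs <- apply(profiles, 2, stats::quantile, probs = c(p[1], 0.5, p[2]),
              names = FALSE, type = 7)
  band <- data.frame(time = times, lower = qs[1, ], median = qs[2, ],
                     upper = qs[3, ])
  coverage <- NA_real_
  if (!is.null(observed)) {
    idx <- match(observed$time, times)
    if (anyNA(idx)) {
      stop("observed times must lie on the simulation grid", call. = FALSE)
    }
    inside <- observed$conc >= band$lower[idx] &
      observed$conc <= band$upper[idx]
    coverage <- mean(inside)
  }
  list(band = band, coverage = coverage)
}
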