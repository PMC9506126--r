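#' Non-compartmental analysis of a concentration-time profile
#'
#' Computes the standard model-free exposure metrics from a single
#' concentration-time curve: area under the curve to the last sample by the
#' linear-up/log-down trapezoidal rule, the terminal elimination rate
#' constant by unweighted log-linear least squares on the last
#' `lambda_z_points` positive samples, extrapolated AUC, maximum
#' concentration, terminal half-life, clearance and the concentration at
#' the end of the profile.
#'
#' @param times Sampling times (h), strictly increasing.
#' @param conc Concentrations (ng/mL), same length as `times`.
#' @param dose Dose (mg); needed for clearance.
#' @param body_weight Body weight (kg); needed for weight-normalised
#'   clearance.
#' @param lambda_z_points Number of terminal samples for the log-linear
#'   regression (default 4).
#' @param method AUC method: `"lin-up-log-down"` (default) or `"linear"`.
#' @return An object of class `"nca"`: a list with `auc_0_t`, `auc_inf`
#'   (ng·h/mL), `cmax`, `c_tend` (ng/mL), `tmax` (h), `lambda_z` (1/h),
#'   `t_half` (h), and `cl` (mL/min/kg, `NA` without dose and weight).
#' @examples
#' t <- seq(0, 72, by = 2)
#' nca(t, 100 * exp(-0.1 * t), dose = 5, body_weight = 70)
#' @export
nca <- function(times, conc, dose = NA_real_, body_weight = NA_real_,
                lambda_z_points = 4,
                method = c("lin-up-log-down", "linear")) {
  method <- match.arg(method)
  stopifnot(length(times) == length(conc))
  keep <- is.finite(conc)
  times <- times[keep]; conc <- conc[keep]
  if (any(diff(times) <= 0)) stop("'times' must be strictly increasing",
                                  call. = FALSE)
  if (sum(conc > 0) < 4) {
    stop("need at least 4 positive concentrations", call. = FALSE)
  }
  auc_0_t <- auc_trapezoid(times, conc, method)
  n <- length(conc)
  tail_idx <- which(conc > 0)
  tail_idx <- tail_idx[tail_idx > max(tail_idx) - lambda_z_points]
  if (length(tail_idx) < 2) stop("too few points for lambda_z", call. = FALSE)
  fit <- stats::lm.fit(cbind(1, times[tail_idx]), log(conc[tail_idx]))
  lambda_z <- -fit$coefficients[[2]]
  if (!is.finite(lambda_z) || lambda_z <= 0) {
    stop("terminal phase is not declining: lambda_z estimation failed ",
         sprintf("(slope %.3g over t = %.3g..%.3g h)",
                 -lambda_z, times[tail_idx[1]], times[max(tail_idx)]),
         call. = FALSE)
  }
  c_last <- conc[max(tail_idx)]
  auc_inf <- auc_0_t + c_last / lambda_z
  cl <- if (is.finite(dose) && is.finite(body_weight)) {
    # dose [mg] -> ng; AUC [ng·h/mL] -> CL mL/h -> mL/min/kg
    dose * 1e6 / auc_inf / 60 / body_weight
  } else NA_real_
  structure(
    list(auc_0_t = auc_0_t, auc_inf = auc_inf,
         cmax = max(conc), tmax = times[which.max(conc)],
         lambda_z = lambda_z, t_half = log(2) / lambda_z,
         cl = cl, c_tend = conc[n],
         dose = dose, body_weight = body_weight,
         n_points = n, lambda_z_points = length(tail_idx)),
    class = "nca"
  )
}

# AUC by trapezoids; "lin-up-log-down" uses the logarithmic trapezoid on
# strictly declining positive segments.
auc_trapezoid <- function(times, conc, method) {
  dt <- diff(times)
  c1 <- conc[-length(conc)]
  c2 <- conc[-1]
  lin <- dt * (c1 + c2) / 2
  if (method == "lin-up-log-down") {
    dn <- c2 < c1 & c2 > 0 & c1 > 0
    lin[dn] <- dt[dn] * (c1[dn] - c2[dn]) / log(c1[dn] / c2[dn])
  }
  sum(lin)
}

#' @export
print.nca <- function(x, ...) {
  cat("<nca>\n")
  cat(sprintf("  AUC_0-t  %10.4g ng.h/mL\n", x$auc_0_t))
  cat(sprintf("  AUC_inf  %10.4g ng.h/mL\n", x$auc_inf))
  cat(sprintf("  Cmax     %10.4g ng/mL (tmax %g h)\n", x$cmax, x$tmax))
  cat(sprintf("  t1/2     %10.4g h (lambda_z %.4g 1/h, %d points)\n",
              x$t_half, x$lambda_z, x$lambda_z_points))
  if (is.finite(x$cl)) cat(sprintf("  CL       %10.4g mL/min/kg\n", x$cl))
  cat(sprintf("  C_tEnd   %10.4g ng/mL\n", x$c_tend))
  invisible(x)
}

#' @export
as.data.frame.nca <- function(x, ...) {
  data.frame(auc_0_t = x$auc_0_t, auc_inf = x$auc_inf, cmax = x$cmax,
             tmax = x$tmax, lambda_z = x$lambda_z, t_half = x$t_half,
             cl = x$cl, c_tend = x$c_tend, dose = x$dose,
             body_weight = x$body_weight)
}
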