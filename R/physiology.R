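# Reference adult physiology (male, 30 y, 70 kg, 176 cm).
# Organ volumes and regional blood flows are standard reference-human values
# (ICRP 89 organ masses; regional flows as fractions of a resting cardiac
# output of 6.5 L/min, after Williams & Leggett 1989 and the PBPK tutorial
# literature).  Flows are the fractions of cardiac output perfusing each
# tissue; gut and spleen drain into the portal vein, which joins the hepatic
# artery at the liver.
.ref_bw <- 70        # kg
.ref_height <- 176   # cm
.ref_co <- 6.5 * 60  # cardiac output, L/h

.ref_organs <- data.frame(
  organ = c("lung", "adipose", "bone", "brain", "gut", "heart", "kidney",
            "liver", "muscle", "skin", "spleen", "rest"),
  volume = c(0.53, 13.5, 8.5, 1.45, 1.1, 0.33, 0.31,
             1.80, 29.0, 3.3, 0.15, 3.0),            # L
  flow_frac = c(1.00, 0.050, 0.050, 0.120, 0.150, 0.040, 0.190,
                0.065, 0.170, 0.050, 0.030, 0.085),  # fraction of CO
  stringsAsFactors = FALSE
)
# liver flow_frac is the hepatic-artery share only; total hepatic perfusion
# adds the portal (gut + spleen) drainage.

.ref_blood <- c(venous = 3.4, arterial = 1.8)  # L

# Tissue composition for Rodgers-Rowland partitioning: fractional water
# (extra-/intracellular), neutral lipid and neutral phospholipid, and
# acidic phospholipid content (mg/g tissue), from the published
# composition tables for the standard organ set.
.tissue_composition <- data.frame(
  organ = c("lung", "adipose", "bone", "brain", "gut", "heart", "kidney",
            "liver", "muscle", "skin", "spleen", "rest"),
  f_ew = c(0.336, 0.135, 0.100, 0.162, 0.282, 0.320, 0.273,
           0.161, 0.118, 0.382, 0.207, 0.250),
  f_iw = c(0.446, 0.017, 0.346, 0.620, 0.475, 0.456, 0.483,
           0.573, 0.630, 0.291, 0.579, 0.480),
  f_nl = c(0.022, 0.853, 0.017, 0.039, 0.038, 0.014, 0.012,
           0.014, 0.010, 0.060, 0.0077, 0.020),
  f_np = c(0.013, 0.0016, 0.0017, 0.0015, 0.0125, 0.011, 0.024,
           0.024, 0.0072, 0.0044, 0.0113, 0.010),
  ap = c(3.91, 0.40, 0.67, 0.40, 2.41, 2.25, 5.03,
         4.56, 1.53, 1.32, 3.18, 2.00),
  stringsAsFactors = FALSE
)

# erythrocyte composition (intracellular only) for the blood-cell branch
.rbc_composition <- list(f_iw = 0.603, f_nl = 0.0017, f_np = 0.0029,
                         ap = 0.5, ph = 7.2)

#' Build a reference virtual individual
#'
#' Constructs the physiology of one adult: organ volumes and regional blood
#' flows scaled from an embedded reference adult (70 kg, 176 cm) to the
#' requested body size, glomerular filtration rate, hepatic scaling
#' constants, haematocrit and plasma-protein state.  Non-adipose organ
#' volumes and the blood pool scale linearly with body weight; adipose takes
#' up the remaining body volume (body density ~1 kg/L) so that total organ
#' volume tracks body volume.  Blood flows and GFR scale allometrically with
#' exponent 0.75.  The construction is deterministic.
#'
#' @param sex `"male"` or `"female"` (kept as metadata; the embedded
#'   reference table is sex-independent).
#' @param age Age in years.  Validated against the adult range 18-70 unless
#'   `override = TRUE`.
#' @param body_weight Body weight (kg), validated against 43-92 kg unless
#'   `override = TRUE`.
#' @param height Height (cm).
#' @param mppgl Microsomal protein per gram liver (mg/g), default 40.
#' @param cppgl Cytosolic protein per gram liver (mg/g), default 75.4.
#' @param plasma_protein_scale Relative binding-protein concentration
#'   (1 = healthy).  Values above 1 describe increased binding capacity
#'   (e.g. the acute-phase response of tuberculosis); see
#'   [scale_fraction_unbound()].
#' @param pathway_activity Named numeric vector of per-enzyme activity
#'   multipliers (default all 1).
#' @param override Allow demographics outside the validated adult ranges.
#' @return An object of class `"physiology"`.
#' @examples
#' p <- reference_individual()
#' sum(p$organs$flow[p$organs$organ != "lung"])  # equals cardiac output
#' @export
reference_individual <- function(sex = "male", age = 30, body_weight = 70.5,
                                 height = 176, mppgl = 40, cppgl = 75.4,
                                 plasma_protein_scale = 1,
                                 pathway_activity = NULL,
                                 override = FALSE) {
  if (!override) {
    if (age < 18 || age > 70) {
      stop("age outside the validated adult range 18-70; ",
           "use override = TRUE to force", call. = FALSE)
    }
    if (body_weight < 43 || body_weight > 92) {
      stop("body weight outside the validated range 43-92 kg; ",
           "use override = TRUE to force", call. = FALSE)
    }
  }
  if (plasma_protein_scale <= 0) {
    stop("'plasma_protein_scale' must be positive", call. = FALSE)
  }
  wr <- body_weight / .ref_bw
  org <- .ref_organs
  # linear volume scaling for lean organs; adipose fills the remainder
  org$volume <- org$volume * wr
  blood <- .ref_blood * wr
  lean <- sum(org$volume[org$organ != "adipose"]) + sum(blood)
  org$volume[org$organ == "adipose"] <-
    max(0.10 * body_weight, body_weight / 1.0 - lean)
  co <- .ref_co * wr^0.75
  org$flow <- org$flow_frac * co
  act <- c(CYP3A4 = 1, CBR1 = 1, UGT1A4 = 1, UGT1A9 = 1, UGT2B7 = 1)
  if (!is.null(pathway_activity)) {
    act[names(pathway_activity)] <- pathway_activity
  }
  structure(
    list(sex = sex, age = age, body_weight = body_weight, height = height,
         organs = org[, c("organ", "volume", "flow")],
         blood = blood,
         cardiac_output = co,
         hematocrit = 0.45,
         gfr = 110 * wr^0.75,            # mL/min
         liver_weight = 1800 * wr,       # g (density 1 g/mL)
         mppgl = mppgl, cppgl = cppgl,
         plasma_protein_scale = plasma_protein_scale,
         pathway_activity = act,
         tissue_composition = .tissue_composition),
    class = "physiology"
  )
}

#' @export
print.physiology <- function(x, ...) {
  cat(sprintf("<physiology> %s, %g y, %g kg, %g cm\n",
              x$sex, x$age, x$body_weight, x$height))
  cat(sprintf("  cardiac output %.1f L/h, GFR %.1f mL/min, liver %.0f g, hct %.2f\n",
              x$cardiac_output, x$gfr, x$liver_weight, x$hematocrit))
  cat(sprintf("  MPPGL %g, CPPGL %g mg/g; plasma protein scale %.3g\n",
              x$mppgl, x$cppgl, x$plasma_protein_scale))
  if (any(x$pathway_activity != 1)) {
    cat("  pathway activity:",
        paste(names(x$pathway_activity),
              signif(x$pathway_activity, 3), sep = "=", collapse = " "), "\n")
  }
  invisible(x)
}

#' Sample a virtual population
#'
#' Draws `n` individuals with body weight and age sampled from the study
#' demographic ranges and per-enzyme activity multipliers sampled
#' log-normally around 1 to represent interindividual variability in
#' metabolic capacity.
#'
#' @param n Number of individuals, >= 1.
#' @param weight_range,age_range Two-element numeric ranges.
#' @param height Height in cm (fixed across the population).
#' @param cv Coefficient of variation of the log-normal pathway-activity
#'   multipliers (default 0.45).  `cv = 0` gives all-1 multipliers.
#' @param demography `"uniform"` (default) or `"truncnorm"`: how weight and
#'   age are drawn within their ranges (the truncated normal uses the range
#'   midpoint as mean and a quarter range as SD).
#' @param seed Integer seed; sampling is reproducible for a fixed seed.
#' @param ... Passed on to [reference_individual()].
#' @return A list of `"physiology"` objects (class `"population"`).
#' @export
sample_population <- function(n, weight_range = c(56, 92),
                              age_range = c(18, 50), height = 176,
                              cv = 0.45, demography = c("uniform", "truncnorm"),
                              seed, ...) {
  stopifnot(n >= 1)
  if (cv < 0) stop("'cv' must be non-negative", call. = FALSE)
  demography <- match.arg(demography)
  if (missing(seed)) stop("'seed' is required", call. = FALSE)
  set.seed(seed)
  draw <- function(rng) {
    if (demography == "uniform") {
      stats::runif(n, rng[1], rng[2])
    } else {
      m <- mean(rng); s <- diff(rng) / 4
      pmin(pmax(stats::rnorm(n, m, s), rng[1]), rng[2])
    }
  }
  bw <- draw(weight_range)
  age <- draw(age_range)
  sdlog <- sqrt(log(1 + cv^2))
  enz <- c("CYP3A4", "CBR1", "UGT1A4", "UGT1A9", "UGT2B7")
  pop <- lapply(seq_len(n), function(i) {
    mult <- stats::setNames(
      if (cv > 0) stats::rlnorm(length(enz), -sdlog^2 / 2, sdlog)
      else rep(1, length(enz)), enz)
    ind <- reference_individual(age = age[i], body_weight = bw[i],
                                height = height, pathway_activity = mult,
                                override = TRUE, ...)
    ind$id <- i
    ind
  })
  class(pop) <- "population"
  pop
}

#' @export
print.population <- function(x, ...) {
  bw <- vapply(x, `[[`, numeric(1), "body_weight")
  cat(sprintf("<population> %d individuals, weight %.1f-%.1f kg\n",
              length(x), min(bw), max(bw)))
  invisible(x)
}

#' Export a population to a data frame
#'
#' One row per individual: id, demographics and pathway multipliers.
#'
#' @param pop A `"population"` from [sample_population()].
#' @return A data.frame.
#' @export
population_table <- function(pop) {
  stopifnot(inherits(pop, "population"))
  do.call(rbind, lapply(pop, function(ind) {
    data.frame(id = ind$id, sex = ind$sex, age = ind$age,
               body_weight = ind$body_weight, height = ind$height,
               t(ind$pathway_activity))
  }))
}

#' Scale a plasma fraction unbound for altered binding-protein levels
#'
#' When the concentration of the binding protein changes by a factor
#' `scale` while the binding affinity is unchanged, the bound:free ratio
#' scales with the protein level and the new fraction unbound is
#' \deqn{f_u' = \frac{f_u}{f_u + scale \, (1 - f_u)}.}
#' `scale = 1` returns `fu` unchanged; `scale > 1` (more binding protein,
#' e.g. the alpha-1-acid-glycoprotein acute-phase response of tuberculosis)
#' lowers the free fraction; `scale < 1` (hypoproteinaemia) raises it.
#'
#' @param fu Baseline fraction unbound, in (0, 1].
#' @param scale Relative binding-protein concentration, > 0.
#' @return Adjusted fraction unbound.
#' @examples
#' scale_fraction_unbound(0.085, 1)    # 0.085
#' scale_fraction_unbound(0.085, 0.5)  # 0.1537
#' @export
scale_fraction_unbound <- function(fu, scale) {
  if (any(fu <= 0) || any(fu > 1)) {
    stop("'fu' must be in (0, 1]", call. = FALSE)
  }
  if (any(scale <= 0)) stop("'scale' must be positive", call. = FALSE)
  fu / (fu + scale * (1 - fu))
}
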