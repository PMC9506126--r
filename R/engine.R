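# Whole-body ODE engine.
#
# State layout, per compound (offset o):
#   o+ 1..12  tissue amounts (µmol), organ order of .ref_organs
#   o+13      venous blood, o+14 arterial blood
#   o+15..32  gut lumen: stomach solid/dissolved, 7 SI segments solid,
#             7 SI dissolved, colon solid/dissolved
#   o+33      cumulative faecal loss, o+34 cumulative renal excretion,
#   o+35      cumulative additional hepatic clearance,
#   o+36..    cumulative amount per metabolic pathway
#
# All amounts in µmol, time in h, concentrations µmol/L; venous plasma
# output converted to ng/mL via the molecular weight.

.idx_arterial <- c(2:7, 9:12)   # arterially fed organs except liver
.idx_venous <- c(2, 3, 4, 6, 7, 9, 10, 12)  # drain directly to venous blood
.i_lung <- 1L; .i_gut <- 5L; .i_liver <- 8L; .i_spleen <- 11L

# Precompute everything the RHS needs for one individual.
build_engine <- function(model, phys) {
  s <- model$settings
  cnames <- vapply(model$compounds, `[[`, character(1), "name")
  nc <- length(cnames)
  org <- phys$organs
  V <- org$volume
  Q <- org$flow
  co <- phys$cardiac_output
  gfr_L_h <- phys$gfr * 60 / 1000

  cpar <- vector("list", nc)
  np <- integer(nc)
  for (k in seq_len(nc)) {
    cp <- model$compounds[[k]]
    bp <- blood_plasma_ratio(cp, s$blood_plasma)
    fu <- scale_fraction_unbound(cp$fraction_unbound,
                                 phys$plasma_protein_scale)
    kp <- effective_kp(cp, phys, s)
    # recompute Kp with the disease-adjusted fu (Kp scales with fu)
    if (is.null(s$kp_override) && phys$plasma_protein_scale != 1) {
      kp <- kp / cp$fraction_unbound * fu
    }
    vmax <- effective_vmax(cp, phys, s)
    km <- vapply(cp$pathways, `[[`, numeric(1), "km")
    prod_idx <- vapply(cp$pathways, function(p) {
      if (p$product == "sink") 0L else match(p$product, cnames)
    }, integer(1))
    np[k] <- length(cp$pathways)
    cpar[[k]] <- list(
      name = cp$name, mw = cp$molecular_weight,
      fu = fu, bp = bp,
      V = V, Q = Q, kpb = unname(kp) / bp,
      q_liver_out = Q[.i_liver] + Q[.i_gut] + Q[.i_spleen],
      renal_cl = cp$gfr_fraction * gfr_L_h * fu,
      addcl = cp$additional_hepatic_clearance * phys$body_weight * 60 / 1000,
      vmax = unname(vmax), km = unname(km), prod_idx = prod_idx,
      caps = lumen_solubility_caps(cp),
      ka = lumen_absorption_rates(cp, s$area_multiplier))
  }
  block <- 35L + np
  off <- c(0L, cumsum(block))[seq_len(nc)]
  nstate <- sum(block)

  # dosing -> instantaneous oral additions and infusion windows
  orals <- list(); infusions <- list()
  for (d in model$dosing) {
    k <- if (is.null(d$compound)) 1L else match(d$compound, cnames)
    amt_mg <- if (d$unit == "mg/kg") d$amount * phys$body_weight else d$amount
    umol <- amt_mg / cpar[[k]]$mw * 1000
    if (d$route == "oral") {
      orals[[length(orals) + 1L]] <- list(t = d$start, k = k, umol = umol)
    } else {
      dur <- if (d$route == "iv_bolus") 1 / 60 else d$infusion_duration
      infusions[[length(infusions) + 1L]] <-
        list(t0 = d$start, t1 = d$start + dur, rate = umol / dur, k = k)
    }
  }

  list(nc = nc, cpar = cpar, off = off, np = np, nstate = nstate,
       co = co, v_ven = phys$blood[["venous"]], v_art = phys$blood[["arterial"]],
       orals = orals, infusions = infusions,
       dissolution = s$dissolution,
       dose_umol = vapply(seq_len(nc), function(k) {
         sum(vapply(c(orals, infusions), function(e) {
           if (identical(e$k, k)) {
             if (!is.null(e$umol)) e$umol else e$rate * (e$t1 - e$t0)
           } else 0
         }, numeric(1)))
       }, numeric(1)))
}

# RHS closure over an engine; `iv_rate` is the per-compound infusion rate
# (µmol/h into venous blood), constant within an integration segment.
engine_rhs <- function(eng) {
  kst <- .gi$k_stomach; ksi <- .gi$k_si; kcol <- .gi$k_colon
  kdiss <- .gi$k_diss
  co <- eng$co; v_ven <- eng$v_ven; v_art <- eng$v_art
  function(t, y, parms) {
    iv_rate <- parms
    dy <- numeric(length(y))
    form <- numeric(eng$nc)
    for (k in seq_len(eng$nc)) {
      ck <- eng$cpar[[k]]
      o <- eng$off[k]
      A <- y[(o + 1):(o + 14)]
      C <- A[1:12] / ck$V
      cout <- C / ck$kpb
      c_ven <- A[13] / v_ven
      c_art <- A[14] / v_art

      # gut lumen
      L <- y[(o + 15):(o + 32)]
      st_s <- L[1]; st_d <- L[2]
      si_s <- L[3:9]; si_d <- L[10:16]
      co_s <- L[17]; co_d <- L[18]
      diss_st <- kdiss * st_s * max(0, 1 - st_d / ck$caps[1])
      diss_si <- kdiss * si_s * pmax(0, 1 - si_d / ck$caps[2:8])
      diss_co <- kdiss * co_s * max(0, 1 - co_d / ck$caps[9])
      abs_si <- ck$ka[1:7] * si_d
      abs_co <- ck$ka[8] * co_d
      dlum <- c(
        -diss_st - kst * st_s,
        diss_st - kst * st_d,
        c(kst * st_s, ksi * si_s[1:6]) - ksi * si_s - diss_si,
        c(kst * st_d, ksi * si_d[1:6]) + diss_si - ksi * si_d - abs_si,
        ksi * si_s[7] - kcol * co_s - diss_co,
        ksi * si_d[7] + diss_co - kcol * co_d - abs_co)
      abs_flux <- sum(abs_si) + abs_co

      # liver metabolism on unbound liver-water concentration
      cu <- ck$fu * cout[.i_liver] / ck$bp
      v <- ck$vmax * cu / (ck$km + cu)
      addr <- ck$addcl * cout[.i_liver] / ck$bp
      renal <- ck$renal_cl * c_art / ck$bp

      d <- numeric(14)
      d[.i_lung] <- co * (c_ven - cout[.i_lung])
      d[.idx_arterial] <- ck$Q[.idx_arterial] * (c_art - cout[.idx_arterial])
      d[.i_liver] <- ck$Q[.i_liver] * c_art +
        ck$Q[.i_gut] * cout[.i_gut] + ck$Q[.i_spleen] * cout[.i_spleen] -
        ck$q_liver_out * cout[.i_liver] - sum(v) - addr + abs_flux
      d[13] <- sum(ck$Q[.idx_venous] * cout[.idx_venous]) +
        ck$q_liver_out * cout[.i_liver] - co * c_ven + iv_rate[k]
      d[14] <- co * cout[.i_lung] - sum(ck$Q[2:12]) * c_art - renal

      dy[(o + 1):(o + 14)] <- d
      dy[(o + 15):(o + 32)] <- dlum
      dy[o + 33] <- kcol * (co_s + co_d)
      dy[o + 34] <- renal
      dy[o + 35] <- addr
      if (eng$np[k] > 0) {
        dy[(o + 36):(o + 35 + eng$np[k])] <- v
        tr <- ck$prod_idx > 0
        if (any(tr)) {
          for (j in which(tr)) form[ck$prod_idx[j]] <- form[ck$prod_idx[j]] + v[j]
        }
      }
    }
    if (any(form > 0)) {
      for (k in seq_len(eng$nc)) {
        dy[eng$off[k] + .i_liver] <- dy[eng$off[k] + .i_liver] + form[k]
      }
    }
    list(dy)
  }
}

# Integrate one individual.  Returns list(times, state matrix, engine).
integrate_individual <- function(model, phys) {
  eng <- build_engine(model, phys)
  s <- model$settings
  dur <- model$duration
  grid <- seq(0, dur, by = 1 / s$output_resolution)
  edges <- sort(unique(c(0, dur,
    vapply(eng$orals, `[[`, numeric(1), "t"),
    unlist(lapply(eng$infusions, function(i) c(i$t0, i$t1))))))
  edges <- edges[edges >= 0 & edges <= dur]
  rhs <- engine_rhs(eng)
  y <- numeric(eng$nstate)
  out_t <- numeric(0); out_y <- NULL
  for (seg in seq_len(length(edges) - 1)) {
    t0 <- edges[seg]; t1 <- edges[seg + 1]
    for (ev in eng$orals) {
      if (isTRUE(all.equal(ev$t, t0))) {
        o <- eng$off[ev$k]
        slot <- if (eng$dissolution == "instant") o + 16 else o + 15
        y[slot] <- y[slot] + ev$umol
      }
    }
    mid <- (t0 + t1) / 2
    rate <- numeric(eng$nc)
    for (inf in eng$infusions) {
      if (inf$t0 <= mid && mid < inf$t1) rate[inf$k] <- rate[inf$k] + inf$rate
    }
    tseg <- sort(unique(c(t0, grid[grid > t0 & grid < t1], t1)))
    sol <- deSolve::lsoda(y, tseg, rhs, parms = rate,
                          rtol = s$rtol, atol = s$atol, maxsteps = 50000)
    if (attr(sol, "istate")[1] < 0) {
      stop("ODE solver failed between t = ", t0, " and ", t1, " h",
           call. = FALSE)
    }
    y <- sol[nrow(sol), -1]
    keep <- if (seg < length(edges) - 1) -nrow(sol) else seq_len(nrow(sol))
    out_t <- c(out_t, sol[keep, 1])
    out_y <- rbind(out_y, sol[keep, -1, drop = FALSE])
  }
  # restrict to the regular grid for reporting
  on_grid <- out_t %in% grid | vapply(out_t, function(t)
    any(abs(t - grid) < 1e-9), logical(1))
  list(times = out_t[on_grid], state = out_y[on_grid, , drop = FALSE],
       engine = eng)
}

#' Simulate a PBPK model
#'
#' Integrates the whole-body system and returns venous plasma
#' concentration-time profiles (ng/mL) for every compound.  For a
#' population physiology each individual is simulated and the pointwise
#' mean and 5th/95th percentile bands are attached.
#'
#' @param object A [pbpk_model()].
#' @param nsim Unused (one deterministic trajectory per individual).
#' @param seed Unused; population variability is fixed when the population
#'   is sampled.
#' @param ... Unused.
#' @return For a single individual, a `"pbpk_sim"`: list with `times` (h),
#'   `conc` (named list of venous plasma profiles, ng/mL), the raw `state`
#'   matrix and the engine internals (for [mass_balance()]).  For a
#'   population, a `"pbpk_popsim"` with per-individual profile matrices and
#'   percentile `bands`.
#' @importFrom stats simulate
#' @method simulate pbpk_model
#' @export
simulate.pbpk_model <- function(object, nsim = 1, seed = NULL, ...) {
  phys <- object$physiology
  if (inherits(phys, "population")) {
    sims <- lapply(phys, function(ind) {
      one <- object; one$physiology <- ind
      simulate.pbpk_model(one)
    })
    times <- sims[[1]]$times
    cnames <- names(sims[[1]]$conc)
    profiles <- lapply(cnames, function(nm) {
      do.call(rbind, lapply(sims, function(s) s$conc[[nm]]))
    })
    names(profiles) <- cnames
    bands <- lapply(profiles, function(m) {
      data.frame(time = times,
                 mean = colMeans(m),
                 p5 = apply(m, 2, stats::quantile, 0.05, names = FALSE),
                 p50 = apply(m, 2, stats::quantile, 0.5, names = FALSE),
                 p95 = apply(m, 2, stats::quantile, 0.95, names = FALSE))
    })
    return(structure(list(times = times, profiles = profiles, bands = bands,
                          individuals = sims, model = object),
                     class = "pbpk_popsim"))
  }
  res <- integrate_individual(object, phys)
  eng <- res$engine
  conc <- lapply(seq_len(eng$nc), function(k) {
    ck <- eng$cpar[[k]]
    c_ven_blood <- res$state[, eng$off[k] + 13] / eng$v_ven
    c_ven_blood / ck$bp * ck$mw   # µmol/L -> ng/mL via MW
  })
  names(conc) <- vapply(eng$cpar, `[[`, character(1), "name")
  structure(list(times = res$times, conc = conc, state = res$state,
                 engine = eng, model = object),
            class = "pbpk_sim")
}

#' @export
print.pbpk_sim <- function(x, ...) {
  cat("<pbpk_sim>", length(x$times), "time points over",
      max(x$times), "h\n")
  for (nm in names(x$conc)) {
    cat(sprintf("  %s: Cmax %.4g ng/mL\n", nm, max(x$conc[[nm]])))
  }
  invisible(x)
}

#' @export
as.data.frame.pbpk_sim <- function(x, ...) {
  do.call(rbind, lapply(names(x$conc), function(nm) {
    data.frame(time_h = x$times, compound = nm, label = "individual",
               conc_ng_per_mL = x$conc[[nm]])
  }))
}

#' @export
as.data.frame.pbpk_popsim <- function(x, ...) {
  do.call(rbind, lapply(names(x$bands), function(nm) {
    b <- x$bands[[nm]]
    do.call(rbind, lapply(c("mean", "p5", "p50", "p95"), function(lab) {
      data.frame(time_h = b$time, compound = nm, label = lab,
                 conc_ng_per_mL = b[[lab]])
    }))
  }))
}

#' @export
plot.pbpk_sim <- function(x, compound = names(x$conc)[1], log = "y", ...) {
  conc <- x$conc[[compound]]
  pos <- conc > 0
  graphics::plot(x$times[pos], conc[pos], type = "l", log = log,
                 xlab = "time (h)", ylab = "plasma concentration (ng/mL)",
                 main = compound, ...)
  invisible(x)
}

#' @export
plot.pbpk_popsim <- function(x, compound = names(x$bands)[1], log = "y", ...) {
  b <- x$bands[[compound]]
  pos <- b$mean > 0
  graphics::plot(b$time[pos], b$mean[pos], type = "l", log = log,
                 xlab = "time (h)", ylab = "plasma concentration (ng/mL)",
                 main = compound, ...)
  graphics::lines(b$time[pos], pmax(b$p5[pos], .Machine$double.xmin), lty = 2)
  graphics::lines(b$time[pos], b$p95[pos], lty = 2)
  invisible(x)
}

#' Mass-balance report of a completed simulation
#'
#' Accounts for the administered dose of each compound at a given time:
#' amount still in the systemic circulation and tissues, amount in the gut
#' lumen, cumulative faecal loss, cumulative renal excretion, cumulative
#' amount through each metabolic pathway (transfer pathways feed the
#' partner compound; sink pathways are terminal), and the additional
#' hepatic clearance pool.  Molar totals over both compounds conserve the
#' dose exactly up to solver tolerance.
#'
#' @param sim A `"pbpk_sim"`.
#' @param at Report time (h); defaults to the end of the simulation.
#' @return An object of class `"mass_balance"`: per-compound lists of
#'   amounts (µmol) and dose fractions, plus the overall molar balance
#'   `total_fraction` (should be 1).
#' @export
mass_balance <- function(sim, at = NULL) {
  stopifnot(inherits(sim, "pbpk_sim"))
  eng <- sim$engine
  i <- if (is.null(at)) length(sim$times) else which.min(abs(sim$times - at))
  y <- unname(sim$state[i, ])
  out <- list()
  total_dose <- sum(eng$dose_umol)
  accounted <- 0
  for (k in seq_len(eng$nc)) {
    o <- eng$off[k]
    ck <- eng$cpar[[k]]
    body <- sum(y[(o + 1):(o + 14)])
    lumen <- sum(y[(o + 15):(o + 32)])
    feces <- y[o + 33]; renal <- y[o + 34]; addcl <- y[o + 35]
    pw <- if (eng$np[k] > 0) y[(o + 36):(o + 35 + eng$np[k])] else numeric(0)
    names(pw) <- if (eng$np[k] > 0) {
      vapply(sim$model$compounds[[k]]$pathways, function(p)
        paste(p$enzyme, p$reaction, sep = ":"), character(1))
    } else character(0)
    sink <- ck$prod_idx == 0
    accounted <- accounted + body + lumen + feces + renal + addcl +
      sum(pw[sink])
    out[[ck$name]] <- list(
      dose_umol = eng$dose_umol[k], body = body, lumen = lumen,
      feces = feces, renal = renal, additional_clearance = addcl,
      pathways = pw, sink_pathways = pw[sink])
  }
  structure(list(compounds = out, total_dose_umol = total_dose,
                 accounted_umol = accounted,
                 total_fraction = accounted / total_dose,
                 time = sim$times[i]),
            class = "mass_balance")
}

#' @export
print.mass_balance <- function(x, ...) {
  cat(sprintf("<mass_balance> at %g h: %.5f of dose accounted\n",
              x$time, x$total_fraction))
  for (nm in names(x$compounds)) {
    b <- x$compounds[[nm]]
    cat(sprintf("  %s (dose %.4g umol): body %.3g, lumen %.3g, faeces %.3g, renal %.3g, add.CL %.3g\n",
                nm, b$dose_umol, b$body, b$lumen, b$feces, b$renal,
                b$additional_clearance))
    for (p in names(b$pathways)) {
      cat(sprintf("    %-42s %.4g umol\n", p, b$pathways[[p]]))
    }
  }
  invisible(x)
}

#' Terminal disposition fractions of the parent dose
#'
#' Summarises where the parent dose ends after a long simulation: fraction
#' renally excreted unchanged, fraction through each enzyme family
#' (transfer pathways followed through the metabolite's own terminal
#' routes), and fraction remaining in the body/lumen.
#'
#' @param sim A `"pbpk_sim"` of the parent (optionally with its metabolite).
#' @return Named list of dose fractions: `renal`, `CYP3A4`, `UGT`,
#'   `CBR1_formed` (gross reduction flux), `CBR1_recycled` (share returned
#'   by back-oxidation), `metabolite_terminal` (metabolite eliminated
#'   through its own routes), `feces`, `remaining`.
#' @export
disposition_fractions <- function(sim) {
  stopifnot(inherits(sim, "pbpk_sim"))
  mb <- mass_balance(sim)
  eng <- sim$engine
  parent <- mb$compounds[[1]]
  dose <- parent$dose_umol
  pw <- parent$pathways
  enz <- vapply(sim$model$compounds[[1]]$pathways, `[[`, character(1),
                "enzyme")
  cyp <- sum(pw[enz == "CYP3A4"])
  ugt <- sum(pw[grepl("^UGT", enz)])
  cbr <- sum(pw[enz == "CBR1"])
  met_term <- 0; recycled <- 0; met_left <- 0
  if (length(mb$compounds) > 1) {
    met <- mb$compounds[[2]]
    met_term <- met$renal + met$additional_clearance +
      sum(met$sink_pathways)
    recycled <- sum(met$pathways) - sum(met$sink_pathways)
    met_left <- met$body + met$lumen
  }
  remaining <- parent$body + parent$lumen + met_left
  parent$renal <- unname(parent$renal)
  parent$feces <- unname(parent$feces)
  met_term <- unname(met_term)
  list(renal = parent$renal / dose,
       CYP3A4 = cyp / dose,
       UGT = ugt / dose,
       CBR1_formed = cbr / dose,
       CBR1_recycled = recycled / dose,
       metabolite_terminal = met_term / dose,
       feces = parent$feces / dose,
       remaining = remaining / dose)
}
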