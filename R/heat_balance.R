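#' Construct a thermal environment
#'
#' Bundles the four environmental inputs of the heat-balance model:
#' air temperature, mean radiant temperature, relative humidity and air
#' speed. All arguments are vectorised and recycled to a common length.
#'
#' @param air_temp Air temperature in degrees C.
#' @param radiant_temp Mean radiant temperature in degrees C.
#' @param rel_humidity Relative humidity as a fraction in \[0, 1\].
#' @param air_speed Air speed in m/s (>= 0).
#' @return A data frame of class `thermal_environment`.
#' @examples
#' thermal_environment(22, 22, 0.5, 0.1)
#' @export
thermal_environment <- function(air_temp, radiant_temp, rel_humidity, air_speed) {
  n <- max(length(air_temp), length(radiant_temp),
           length(rel_humidity), length(air_speed))
  env <- data.frame(
    air_temp     = rep_len(as.numeric(air_temp), n),
    radiant_temp = rep_len(as.numeric(radiant_temp), n),
    rel_humidity = rep_len(as.numeric(rel_humidity), n),
    air_speed    = rep_len(as.numeric(air_speed), n)
  )
  if (any(!is.finite(as.matrix(env))))
    stop("thermal_environment: all fields must be finite")
  if (any(env$rel_humidity < 0 | env$rel_humidity > 1))
    stop("rel_humidity must be a fraction in [0, 1]")
  if (any(env$air_speed < 0))
    stop("air_speed must be >= 0")
  if (any(env$air_temp < -40 | env$air_temp > 60 |
          env$radiant_temp < -40 | env$radiant_temp > 60))
    stop("temperatures must lie in [-40, 60] degrees C")
  class(env) <- c("thermal_environment", "data.frame")
  env
}

#' Construct an occupant state
#'
#' Personal inputs of the heat-balance model: metabolic rate, external
#' work (zero for ordinary indoor activity) and clothing insulation.
#' Insulation is stored both in clo and in m2K/W.
#'
#' @param met_rate Metabolic rate in W/m2 (> 0).
#' @param clothing_clo Clothing ensemble insulation in clo (>= 0).
#' @param external_work Rate of external mechanical work in W/m2, default 0.
#' @return A data frame of class `occupant_state`.
#' @examples
#' occupant_state(met_rate = met_to_wm2(1.5), clothing_clo = 0.8)
#' @export
occupant_state <- function(met_rate, clothing_clo, external_work = 0) {
  n <- max(length(met_rate), length(clothing_clo), length(external_work))
  occ <- data.frame(
    met_rate      = rep_len(as.numeric(met_rate), n),
    clothing_clo  = rep_len(as.numeric(clothing_clo), n),
    external_work = rep_len(as.numeric(external_work), n)
  )
  if (any(!is.finite(as.matrix(occ))))
    stop("occupant_state: all fields must be finite")
  if (any(occ$met_rate <= 0)) stop("met_rate must be > 0")
  if (any(occ$clothing_clo < 0)) stop("clothing insulation must be >= 0")
  if (any(occ$external_work < 0)) stop("external_work must be >= 0")
  occ$clothing_insulation <- clo_to_insulation(occ$clothing_clo)
  class(occ) <- c("occupant_state", "data.frame")
  occ
}

#' Saturation and partial water vapour pressure
#'
#' `saturation_vapor_pressure()` uses the Antoine-type form
#' p_sat(t) = 1000 * exp(16.6536 - 4030.183 / (t + 235)) Pa, the form
#' used by standard PMV implementations (alternative psychrometric
#' formulae differ by less than 1 % over the indoor range).
#' `vapor_pressure()` multiplies by relative humidity.
#'
#' @param air_temp Air temperature in degrees C.
#' @param rel_humidity Relative humidity as a fraction in \[0, 1\].
#' @return Pressure in Pa.
#' @examples
#' vapor_pressure(22, 0.5)
#' @export
vapor_pressure <- function(air_temp, rel_humidity) {
  if (any(rel_humidity < 0 | rel_humidity > 1))
    stop("rel_humidity must be a fraction in [0, 1]")
  rel_humidity * saturation_vapor_pressure(air_temp)
}

#' @rdname vapor_pressure
#' @export
saturation_vapor_pressure <- function(air_temp) {
  1000 * exp(16.6536 - 4030.183 / (air_temp + 235))
}

#' Clothing area factor
#'
#' Ratio of the clothed to the nude body surface area, from the standard
#' piecewise-linear relation with the branch point at 0.078 m2K/W
#' (about 0.5 clo). The small discontinuity (~3e-4) at the branch point
#' is part of the canonical formulation and is kept.
#'
#' @param insulation Clothing insulation in m2K/W (>= 0).
#' @return Dimensionless factor >= 1.
#' @examples
#' clothing_area_factor(clo_to_insulation(1))
#' @export
clothing_area_factor <- function(insulation) {
  if (any(insulation < 0)) stop("insulation must be >= 0")
  ifelse(insulation <= 0.078,
         1.00 + 1.290 * insulation,
         1.05 + 0.645 * insulation)
}

# Right-hand side of the clothing-surface-temperature balance:
# t_cl = 35.7 - 0.028 (M - W)
#        - I_cl [ 3.96e-8 f_cl ((t_cl+273)^4 - (t_r+273)^4)
#                 + f_cl h_c (t_cl - t_a) ]
# with h_c the larger of the natural and forced convection branches.
tcl_rhs <- function(tcl, ta, tr, icl, fcl, mw, hcf) {
  hc <- pmax(2.38 * abs(tcl - ta)^0.25, hcf)
  rhs <- 35.7 - 0.028 * mw -
    icl * (3.96e-8 * fcl * ((tcl + 273)^4 - (tr + 273)^4) +
             fcl * hc * (tcl - ta))
  list(rhs = rhs, hc = hc)
}

#' Solve the clothing surface temperature
#'
#' The surface temperature of the clothed body is defined implicitly by a
#' balance between conduction through the clothing and radiative plus
#' convective loss from its surface; the convective coefficient itself
#' depends on the surface temperature (natural branch 2.38 |dT|^0.25 vs
#' forced branch 12.1 sqrt(v)). The fixed point is found by damped
#' iteration (next = (current + update)/2) to `tol`; elements that fail
#' to converge within `max_iter` fall back to bisection on the residual
#' and are flagged if that fails too.
#'
#' @param env A [thermal_environment()].
#' @param occ An [occupant_state()].
#' @param tol Convergence tolerance on t_cl in degrees C.
#' @param max_iter Maximum damped-iteration count.
#' @return A data frame with columns `t_cl` (degrees C), `h_c` (W/m2K),
#'   `f_cl`, `forced_convection`, `converged`, `iterations`.
#' @export
solve_clothing_temperature <- function(env, occ, tol = 1e-5, max_iter = 300L) {
  n <- max(nrow(env), nrow(occ))
  ta  <- rep_len(env$air_temp, n)
  tr  <- rep_len(env$radiant_temp, n)
  v   <- rep_len(env$air_speed, n)
  icl <- rep_len(occ$clothing_insulation, n)
  mw  <- rep_len(occ$met_rate - occ$external_work, n)

  fcl <- clothing_area_factor(icl)
  hcf <- 12.1 * sqrt(v)

  tcl <- (35.7 - 0.028 * mw + ta) / 2
  done <- rep(FALSE, n)
  iters <- rep(0L, n)
  hc <- rep(NA_real_, n)
  for (i in seq_len(max_iter)) {
    step <- tcl_rhs(tcl, ta, tr, icl, fcl, mw, hcf)
    tnew <- (tcl + step$rhs) / 2
    delta <- abs(tnew - tcl)
    tcl <- tnew
    hc <- step$hc
    newly <- !done & delta < tol
    iters[newly] <- i
    done <- done | newly
    if (all(done)) break
  }

  # bisection fallback on g(t) = rhs(t) - t for stubborn elements
  for (j in which(!done)) {
    g <- function(t) tcl_rhs(t, ta[j], tr[j], icl[j], fcl[j], mw[j], hcf[j])$rhs - t
    lo <- min(ta[j], tr[j]) - 30; hi <- 70
    if (g(lo) > 0 && g(hi) < 0) {
      for (k in 1:80) {
        mid <- (lo + hi) / 2
        if (g(mid) > 0) lo <- mid else hi <- mid
      }
      tcl[j] <- (lo + hi) / 2
      hc[j] <- tcl_rhs(tcl[j], ta[j], tr[j], icl[j], fcl[j], mw[j], hcf[j])$hc
      iters[j] <- max_iter
      done[j] <- TRUE
    }
  }

  data.frame(
    t_cl = tcl, h_c = hc, f_cl = fcl,
    forced_convection = hcf >= 2.38 * abs(tcl - ta)^0.25,
    converged = done, iterations = iters
  )
}

#' Predicted Mean Vote and Predicted Percentage Dissatisfied
#'
#' `compute_pmv()` evaluates the Fanger heat-balance index
#' PMV = (0.303 exp(-0.036 M) + 0.028) L, where the thermal load L is the
#' difference between internal heat production and the six standard loss
#' terms (skin diffusion, sweat evaporation, respiratory latent and dry
#' loss, radiation and convection from the clothing surface). The sweat
#' term is floored at zero below M - W = 58.15 W/m2. `compute_ppd()` maps
#' PMV to the expected percentage of dissatisfied occupants.
#'
#' @inheritParams solve_clothing_temperature
#' @param pmv A numeric vector of PMV values.
#' @return `compute_pmv()`: a data frame of class `pmv_result` with
#'   columns `pmv`, `ppd`, `t_cl`, `h_c`, `f_cl`, `converged`,
#'   `iterations`. `compute_ppd()`: percentage in \[5, 100\].
#' @examples
#' env <- thermal_environment(22, 22, 0.5, 0.1)
#' occ <- occupant_state(met_to_wm2(1.5), clothing_clo = 0.8)
#' compute_pmv(env, occ)
#' compute_ppd(c(-0.5, 0, 0.5))
#' @export
compute_pmv <- function(env, occ, tol = 1e-5, max_iter = 300L) {
  n <- max(nrow(env), nrow(occ))
  ta <- rep_len(env$air_temp, n)
  tr <- rep_len(env$radiant_temp, n)
  rh <- rep_len(env$rel_humidity, n)
  m  <- rep_len(occ$met_rate, n)
  w  <- rep_len(occ$external_work, n)
  mw <- m - w

  sol <- solve_clothing_temperature(env, occ, tol = tol, max_iter = max_iter)
  pa <- vapor_pressure(ta, rh)

  load <- mw -
    3.05e-3 * (5733 - 6.99 * mw - pa) -          # skin vapour diffusion
    0.42 * pmax(mw - 58.15, 0) -                 # sweat evaporation
    1.7e-5 * m * (5867 - pa) -                   # respiration, latent
    0.0014 * m * (34 - ta) -                     # respiration, dry
    3.96e-8 * sol$f_cl * ((sol$t_cl + 273)^4 - (tr + 273)^4) -  # radiation
    sol$f_cl * sol$h_c * (sol$t_cl - ta)         # convection

  pmv <- (0.303 * exp(-0.036 * m) + 0.028) * load
  out <- data.frame(
    pmv = pmv, ppd = compute_ppd(pmv),
    t_cl = sol$t_cl, h_c = sol$h_c, f_cl = sol$f_cl,
    converged = sol$converged, iterations = sol$iterations
  )
  class(out) <- c("pmv_result", "data.frame")
  out
}

#' @rdname compute_pmv
#' @export
compute_ppd <- function(pmv) {
  100 - 95 * exp(-(0.03353 * pmv^4 + 0.2179 * pmv^2))
}

#' Low-level vectorised PMV
#'
#' Same equation set as [compute_pmv()] on bare numeric vectors,
#' returning only the PMV value. This is the fast path used by the
#' inverse calibration, where the index is evaluated millions of times.
#'
#' @param ta,tr Air and mean radiant temperature, degrees C.
#' @param rh Relative humidity as a fraction.
#' @param v Air speed, m/s.
#' @param met Metabolic rate, W/m2.
#' @param clo Clothing insulation, clo.
#' @param wme External work, W/m2.
#' @inheritParams solve_clothing_temperature
#' @return Numeric vector of PMV values.
#' @examples
#' pmv_engine(22, 22, 0.5, 0.1, met = met_to_wm2(1.5), clo = 0.8)
#' @export
pmv_engine <- function(ta, tr, rh, v, met, clo, wme = 0,
                       tol = 1e-5, max_iter = 300L) {
  n <- max(length(ta), length(tr), length(rh), length(v),
           length(met), length(clo), length(wme))
  ta <- rep_len(ta, n); tr <- rep_len(tr, n); rh <- rep_len(rh, n)
  v <- rep_len(v, n); met <- rep_len(met, n); clo <- rep_len(clo, n)
  wme <- rep_len(wme, n)
  mw <- met - wme
  icl <- clo_to_insulation(clo)
  fcl <- clothing_area_factor(icl)
  hcf <- 12.1 * sqrt(v)
  tcl <- (35.7 - 0.028 * mw + ta) / 2
  for (i in seq_len(max_iter)) {
    step <- tcl_rhs(tcl, ta, tr, icl, fcl, mw, hcf)
    tnew <- (tcl + step$rhs) / 2
    if (max(abs(tnew - tcl)) < tol) { tcl <- tnew; break }
    tcl <- tnew
  }
  hc <- pmax(2.38 * abs(tcl - ta)^0.25, hcf)
  pa <- rh * saturation_vapor_pressure(ta)
  load <- mw -
    3.05e-3 * (5733 - 6.99 * mw - pa) -
    0.42 * pmax(mw - 58.15, 0) -
    1.7e-5 * met * (5867 - pa) -
    0.0014 * met * (34 - ta) -
    3.96e-8 * fcl * ((tcl + 273)^4 - (tr + 273)^4) -
    fcl * hc * (tcl - ta)
  (0.303 * exp(-0.036 * met) + 0.028) * load
}

#' Operative temperature
#'
#' The mean of air and mean radiant temperature. This simple average is
#' only a valid summary of the combined dry heat exchange at low air
#' speed; a warning is emitted when `air_speed` reaches the configured
#' threshold (default 0.2 m/s).
#'
#' @param air_temp Air temperature in degrees C.
#' @param radiant_temp Mean radiant temperature in degrees C.
#' @param air_speed Air speed in m/s.
#' @param warn_threshold Air speed (m/s) at or above which the averaging
#'   is flagged as invalid.
#' @return Operative temperature in degrees C.
#' @examples
#' operative_temperature(19.5, 20.5, 0.1)
#' @export
operative_temperature <- function(air_temp, radiant_temp, air_speed,
                                  warn_threshold = 0.2) {
  if (any(air_speed >= warn_threshold))
    warning(sprintf(
      "operative temperature as the plain mean is only valid below %.2g m/s; %d value(s) at or above",
      warn_threshold, sum(air_speed >= warn_threshold)))
  (air_temp + radiant_temp) / 2
}
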