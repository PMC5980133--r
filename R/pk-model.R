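#' Free drug concentration under the quasi-steady-state approximation
#'
#' Solves the binding equilibrium for the free concentration `C` given the
#' total drug concentration `ctot` and total target concentration `rtot`:
#' `C + rtot * C / (KSS + C) = ctot`. The closed-form root is
#' `C = 0.5 * [(ctot - rtot - KSS) + sqrt((ctot - rtot - KSS)^2 +
#' 4 * KSS * ctot)]`, evaluated in a cancellation-safe form.
#'
#' @param ctot total drug concentration (ug/mL); vectorised.
#' @param rtot total target concentration (target units/L, coupled 1:1 to
#'   ug/mL).
#' @param kss quasi-steady-state constant (ug/mL).
#' @return Free concentration(s), `0 <= C <= ctot`.
#' @examples
#' qss_free_concentration(1, 0, 5.68)     # no target: free == total
#' qss_free_concentration(1, 8.85, 5.68)  # 0.4075
#' @export
qss_free_concentration <- function(ctot, rtot, kss) {
  stopifnot(all(ctot >= 0), all(rtot >= 0), all(kss >= 0))
  b <- ctot - rtot - kss
  s <- sqrt(b * b + 4 * kss * ctot)
  # b >= 0: direct formula is stable; b < 0: rationalised form avoids
  # subtracting nearly equal magnitudes when kss*ctot is small
  cfree <- ifelse(b >= 0, 0.5 * (b + s),
                  2 * kss * ctot / (s - b))
  cfree[ctot == 0] <- 0
  pmin(pmax(cfree, 0), ctot)
}

#' Right-hand side of the PK differential equations
#'
#' State balance of the two-compartment QSS-TMDD model in amounts of drug
#' (`depot`, `cen`, `per`, all mg; `cen` is the total central amount, free
#' plus target-bound) and total target concentration `rtot` (units/L, in
#' the central compartment only). With `C` the free central concentration
#' from [qss_free_concentration()], `Cp = per/VP` and bound complex
#' `RC = rtot * C / (KSS + C)`:
#' \preformatted{
#'   d depot/dt = -KA * depot
#'   d cen/dt   =  KA * depot + rate - CL*C - Q*(C - Cp) - KINT*RC*VC
#'   d per/dt   =  Q * (C - Cp)
#'   d rtot/dt  =  KSYN - KDEG * rtot - (KINT - KDEG) * RC
#' }
#' With `KSYN = 0` and `rtot = 0` this reduces exactly to a linear
#' two-compartment model with first-order absorption.
#'
#' @param state numeric vector `c(depot, cen, per, rtot)`.
#' @param params a [pk_params()] object (`VC` already route-adjusted).
#' @param infusion_rate zero-order input into the central compartment
#'   (mg/day).
#' @return Named derivative vector in state order.
#' @export
pk_rhs <- function(state, params, infusion_rate = 0) {
  depot <- state[[1]]; cen <- state[[2]]; per <- state[[3]]
  rtot <- state[[4]]
  ctot <- cen / params$VC
  C <- qss_free_concentration(ctot, rtot, params$KSS)
  Cp <- per / params$VP
  RC <- if (params$KSS + C > 0) rtot * C / (params$KSS + C) else 0
  abs_in <- params$KA * depot
  c(depot = -abs_in,
    cen = abs_in + infusion_rate - params$CL * C - params$Q * (C - Cp) -
      params$KINT * RC * params$VC,
    per = params$Q * (C - Cp),
    rtot = params$KSYN - params$KDEG * rtot -
      (params$KINT - params$KDEG) * RC)
}

#' Build a dose-event table
#'
#' @param time administration times (days).
#' @param amount dose amounts (mg); recycled.
#' @param route `"IV_BOLUS"`, `"IV_INFUSION"` or `"SC"`; recycled.
#' @param duration infusion duration (days); must be > 0 exactly for
#'   infusions and 0 otherwise.
#' @return A `data.frame` with columns time, amount, route, duration.
#' @export
dose_events <- function(time, amount, route = "IV_BOLUS", duration = 0) {
  d <- data.frame(time = time, amount = amount, route = route,
                  duration = duration, stringsAsFactors = FALSE)
  if (any(d$amount <= 0)) stop("dose amounts must be > 0", call. = FALSE)
  if (any(d$time < 0)) stop("dose times must be >= 0", call. = FALSE)
  if (!all(d$route %in% c("IV_BOLUS", "IV_INFUSION", "SC")))
    stop("unknown route", call. = FALSE)
  bad <- (d$route == "IV_INFUSION") != (d$duration > 0)
  if (any(bad))
    stop("duration must be > 0 exactly for IV_INFUSION doses",
         call. = FALSE)
  d
}

#' Simulate the PK model over a dosing schedule
#'
#' Integrates the QSS-TMDD model with the stiff `lsoda` solver, restarting
#' the integration at every dose time and infusion end. IV bolus doses are
#' instantaneous increments to the central amount; SC doses add
#' `F * amount` to the depot at dose time; infusions are zero-order input
#' over their duration. The target pool starts at its drug-free
#' equilibrium `KSYN/KDEG` (0 when `KSYN = 0`) unless `init_rtot` is
#' given. An observation scheduled exactly at a dose time is reported
#' pre-dose.
#'
#' @param params a [pk_params()] object; `VC` must already reflect the
#'   route covariate where applicable (see [apply_route_covariate()]).
#' @param doses dose-event table from [dose_events()] (may have 0 rows).
#' @param times sorted non-negative observation times (days).
#' @param init_rtot optional initial total target concentration.
#' @param rtol,atol solver tolerances.
#' @return `data.frame` with columns `time`, `ctot` (total central
#'   concentration, ug/mL), `cfree` (free concentration, ug/mL) and
#'   `rtot`.
#' @examples
#' p <- monkey_pk_typical()
#' d <- dose_events(0, 9)  # 3 mg/kg in a 3-kg monkey
#' simulate_pk(p, d, times = c(0.01, 1, 7, 28))
#' @export
simulate_pk <- function(params, doses = NULL, times, init_rtot = NULL,
                        rtol = 1e-8, atol = 1e-10) {
  stopifnot(inherits(params, "pk_params"))
  if (is.null(doses))
    doses <- data.frame(time = numeric(0), amount = numeric(0),
                        route = character(0), duration = numeric(0))
  if (is.unsorted(times)) stop("times must be sorted", call. = FALSE)
  if (any(times < 0)) stop("times must be non-negative", call. = FALSE)
  if (is.null(init_rtot))
    init_rtot <- if (params$KDEG > 0) params$KSYN / params$KDEG else 0
  tmax <- max(times, 0)
  inf <- doses[doses$route == "IV_INFUSION", , drop = FALSE]
  breaks <- sort(unique(c(0, doses$time,
                          if (nrow(inf)) inf$time + inf$duration,
                          tmax)))
  breaks <- breaks[breaks <= tmax]
  if (breaks[length(breaks)] < tmax) breaks <- c(breaks, tmax)

  y <- c(depot = 0, cen = 0, per = 0, rtot = init_rtot)
  Fabs <- bioavailability(params$F_logit)
  out_t <- numeric(0)
  out_y <- NULL
  record <- function(tt, states) {
    out_t <<- c(out_t, tt)
    out_y <<- rbind(out_y, states)
  }

  for (k in seq_along(breaks)) {
    bk <- breaks[k]
    # report pre-dose state at the break itself if requested
    n_here <- sum(times == bk)
    if (n_here > 0)
      record(rep(bk, n_here),
             matrix(rep(y, n_here), nrow = n_here, byrow = TRUE,
                    dimnames = list(NULL, names(y))))
    if (k == length(breaks)) break
    bn <- breaks[k + 1]
    # instantaneous inputs at bk
    here <- doses[doses$time == bk, , drop = FALSE]
    if (nrow(here)) {
      y[["cen"]] <- y[["cen"]] +
        sum(here$amount[here$route == "IV_BOLUS"])
      y[["depot"]] <- y[["depot"]] +
        Fabs * sum(here$amount[here$route == "SC"])
    }
    # constant infusion rate over (bk, bn)
    rate <- 0
    if (nrow(inf)) {
      act <- inf$time <= bk & (inf$time + inf$duration) > bk + 1e-12
      rate <- sum(inf$amount[act] / inf$duration[act])
    }
    seg_times <- times[times > bk & times < bn]
    tt <- unique(c(bk, seg_times, bn))
    sol <- deSolve::ode(y = y, times = tt, func = "pk_derivs",
                        parms = c(params$KA, params$CL, params$VC,
                                  params$Q, params$VP, params$KINT,
                                  params$KSS, params$KSYN, params$KDEG,
                                  rate),
                        dllname = "lymphodep", initfunc = "pk_init",
                        method = "lsoda", rtol = rtol, atol = atol,
                        maxsteps = 20000)
    if (attr(sol, "istate")[1] < 0 || anyNA(sol))
      stop("PK solver failure near t = ", bk, "; state: ",
           paste(signif(y, 6), collapse = ", "), call. = FALSE)
    if (length(seg_times)) {
      idx <- match(seg_times, sol[, "time"])
      record(seg_times, sol[idx, -1, drop = FALSE])
    }
    y <- sol[nrow(sol), -1]
  }

  ord <- order(out_t)
  ctot <- out_y[ord, "cen"] / params$VC
  rt <- out_y[ord, "rtot"]
  data.frame(time = out_t[ord],
             ctot = ctot,
             cfree = qss_free_concentration(ctot, rt, params$KSS),
             rtot = rt,
             row.names = NULL)
}

#' Terminal half-life of the linear two-compartment disposition model
#'
#' Computes `t1/2 = ln(2) / lambda_z` where `lambda_z` is the smaller
#' eigenvalue magnitude of the two-compartment disposition matrix with
#' micro-constants `k10 = CL/VC`, `k12 = Q/VC`, `k21 = Q/VP`.
#'
#' @param CL clearance (L/day).
#' @param VC central volume (L).
#' @param Q intercompartmental clearance (L/day).
#' @param VP peripheral volume (L).
#' @return Terminal half-life (days).
#' @examples
#' terminal_halflife(0.0187, 0.141, 0.127, 0.127)  # about 10.3 days
#' @export
terminal_halflife <- function(CL, VC, Q, VP) {
  stopifnot(CL > 0, VC > 0, Q >= 0, VP > 0)
  k10 <- CL / VC; k12 <- Q / VC; k21 <- Q / VP
  s <- k10 + k12 + k21
  lambda_z <- (s - sqrt(s^2 - 4 * k10 * k21)) / 2
  if (lambda_z <= 0) {
    # Q = 0 degenerates to one compartment
    lambda_z <- k10
  }
  log(2) / lambda_z
}
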