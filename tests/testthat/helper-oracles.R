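# Independent reference implementations used as oracles. These are kept
# deliberately separate from the package's solver paths: closed forms,
# eigen-decompositions and brute-force root finding only.

# linear two-compartment model with first-order depot, solved by matrix
# exponential (eigendecomposition); states: depot, cen, per (amounts)
linear2cpt_matexp <- function(params, doses, times) {
  KA <- params$KA; CL <- params$CL; VC <- params$VC
  Q <- params$Q; VP <- params$VP
  A <- matrix(c(-KA, 0, 0,
                KA, -(CL + Q) / VC, Q / VP,
                0, Q / VC, -Q / VP),
              nrow = 3, byrow = TRUE)
  eg <- eigen(A)
  V <- eg$vectors; Vi <- solve(V)
  expAt <- function(t) Re(V %*% diag(exp(eg$values * t)) %*% Vi)
  Fabs <- plogis(params$F_logit)
  ev <- doses[order(doses$time), , drop = FALSE]
  sapply(times, function(t) {
    y <- c(0, 0, 0)
    tcur <- 0
    for (i in seq_len(nrow(ev))) {
      if (ev$time[i] >= t) break
      y <- as.numeric(expAt(ev$time[i] - tcur) %*% y)
      tcur <- ev$time[i]
      if (ev$route[i] == "IV_BOLUS") y[2] <- y[2] + ev$amount[i]
      if (ev$route[i] == "SC") y[1] <- y[1] + Fabs * ev$amount[i]
    }
    y <- as.numeric(expAt(t - tcur) %*% y)
    y[2] / VC  # central concentration
  })
}

# brute-force QSS root by interval bisection on the conservation relation
qss_root_bisect <- function(ctot, rtot, kss, tol = 1e-14) {
  if (ctot == 0) return(0)
  g <- function(C) C + rtot * C / (kss + C) - ctot
  lo <- 0; hi <- ctot
  while (hi - lo > tol * max(1, ctot)) {
    mid <- (lo + hi) / 2
    if (g(mid) > 0) hi <- mid else lo <- mid
  }
  (lo + hi) / 2
}

# closed-form steady state of the NK turnover model at constant conc
nk_steady_pct <- function(KIN, BL, EMAX, C50, conc) {
  kout <- KIN / BL
  e <- EMAX * conc / (C50 + conc)
  100 * kout / (kout + e)
}

# closed-form steady state of the B transit model at constant conc
b_steady_pct <- function(MTT, EMAX, C50, conc) {
  ktr <- 4 / MTT
  e <- EMAX * conc / (C50 + conc)
  100 * ktr / (ktr + e)
}

typical_bolus_profile <- function(dose = 9, times = c(0.01, seq(1, 42))) {
  simulate_pk(monkey_pk_typical(), dose_events(0, dose), times)
}
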