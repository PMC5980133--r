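test_that("bioavailability is the logistic transform", {
  expect_equal(bioavailability(0), 0.5)
  expect_lt(bioavailability(-30), 1e-12)
  # value consistent with the published estimate
  expect_equal(bioavailability(log(0.227 / 0.773)), 0.227)
  # strictly monotone
  x <- seq(-5, 5, by = 0.5)
  expect_true(all(diff(bioavailability(x)) > 0))
})

test_that("route covariate shrinks VC for SC and only SC", {
  expect_equal(apply_route_covariate(0.141, "IV_BOLUS", -0.697), 0.141)
  expect_equal(apply_route_covariate(0.141, "IV_INFUSION", -0.697), 0.141)
  expect_equal(apply_route_covariate(0.141, "SC", -0.697), 0.0427,
               tolerance = 1e-3)
  expect_equal(apply_route_covariate(0.141, "SC", 0), 0.141)
  expect_error(apply_route_covariate(0.141, "SC", -1.2), "non-positive")
})

test_that("QSS free concentration solves the conservation relation", {
  expect_equal(qss_free_concentration(1, 0, 5.68), 1)
  expect_equal(qss_free_concentration(0, 8.85, 5.68), 0)
  # frozen value from the independent bisection oracle
  expect_equal(qss_free_concentration(1, 8.85, 5.68), 0.4075327,
               tolerance = 1e-6)
  expect_equal(qss_free_concentration(1, 8.85, 5.68),
               qss_root_bisect(1, 8.85, 5.68), tolerance = 1e-10)
  # conservation identity to 1e-10 relative over random inputs
  set.seed(42)
  for (i in 1:200) {
    ctot <- runif(1, 0, 500); rtot <- runif(1, 0, 50)
    kss <- runif(1, 0.1, 50)
    C <- qss_free_concentration(ctot, rtot, kss)
    expect_equal(C + rtot * C / (kss + C), ctot,
                 tolerance = 1e-10)
    expect_true(C >= 0 && C <= ctot)
  }
  # monotone increasing in ctot, decreasing in rtot
  ct <- seq(0, 100, by = 1)
  expect_true(all(diff(qss_free_concentration(ct, 8.85, 5.68)) > 0))
  rt <- seq(0, 50, by = 1)
  expect_true(all(diff(qss_free_concentration(10, rt, 5.68)) < 0))
})

test_that("pk_rhs matches the balance equations term by term", {
  p <- monkey_pk_typical()
  # drug-free steady state: all derivatives vanish
  d0 <- pk_rhs(c(0, 0, 0, p$KSYN / p$KDEG), p)
  expect_equal(unname(d0), rep(0, 4))
  # random states against independent recomputation
  set.seed(7)
  for (i in 1:50) {
    st <- c(runif(1, 0, 5), runif(1, 0, 10), runif(1, 0, 10),
            runif(1, 0, 20))
    rate <- runif(1, 0, 3)
    d <- pk_rhs(st, p, rate)
    C <- qss_root_bisect(st[2] / p$VC, st[4], p$KSS)
    Cp <- st[3] / p$VP
    RC <- st[4] * C / (p$KSS + C)
    expect_equal(unname(d[1]), -p$KA * st[1], tolerance = 1e-9)
    expect_equal(unname(d[2]),
                 p$KA * st[1] + rate - p$CL * C - p$Q * (C - Cp) -
                   p$KINT * RC * p$VC, tolerance = 1e-8)
    expect_equal(unname(d[3]), p$Q * (C - Cp), tolerance = 1e-9)
    expect_equal(unname(d[4]),
                 p$KSYN - p$KDEG * st[4] - (p$KINT - p$KDEG) * RC,
                 tolerance = 1e-9)
  }
})

test_that("with the target pathway off the model is exactly linear", {
  p <- monkey_pk_typical()
  p$KSYN <- 0
  doses <- dose_events(c(0, 10, 21), c(9, 4, 9),
                       c("IV_BOLUS", "SC", "IV_BOLUS"), 0)
  times <- c(0.05, 0.5, 1, 3, 7, 10.5, 12, 15, 21.5, 25, 30, 42)
  sim <- simulate_pk(p, doses, times, rtol = 1e-10, atol = 1e-12)
  oracle <- linear2cpt_matexp(p, doses, times)
  expect_equal(sim$cfree, oracle, tolerance = 1e-6)
  expect_equal(sim$cfree, sim$ctot)  # no binding, free == total
})

test_that("mass is conserved when all elimination is off", {
  p <- pk_params(CL = 1e-12, KSYN = 0, KDEG = 0, KINT = 0)
  p$CL <- 1e-12
  doses <- dose_events(0, 5)
  tt <- c(0.5, 5, 20, 60)
  # inspect amounts via a one-compartment-free reconstruction: total
  # amount = ctot*VC + per; per from Q exchange; use dense rtot output
  sim <- simulate_pk(p, doses, tt, rtol = 1e-10, atol = 1e-12)
  # reconstruct peripheral amount by re-simulating with the same solver
  # is circular; instead check the late-time equilibrium partition:
  # at equilibrium C = Cp, so amount = C*(VC+VP) = 5
  expect_equal(sim$ctot[4] * (p$VC + p$VP), 5, tolerance = 1e-6)
})

test_that("bolus kinetics: initial concentration and superposition", {
  p <- monkey_pk_typical()
  p$KSYN <- 0  # linear regime
  sim <- simulate_pk(p, dose_events(0, 0.9), 1e-6)
  expect_equal(sim$cfree, 0.9 / 0.141, tolerance = 1e-4)
  # two far-apart equal boluses: second peak superposes within 0.1%
  t_obs <- 100 + c(1e-6, 1, 5, 20)
  two <- simulate_pk(p, dose_events(c(0, 100), c(9, 9)), t_obs)
  one <- simulate_pk(p, dose_events(0, 9), t_obs)
  tail1 <- simulate_pk(p, dose_events(0, 9), t_obs - 100)
  expect_equal(two$cfree, one$cfree + tail1$cfree, tolerance = 1e-3)
})

test_that("infusion input integrates to the administered amount", {
  p <- monkey_pk_typical()
  p$KSYN <- 0
  inf <- simulate_pk(p, dose_events(0, 9, "IV_INFUSION", 30 / 60 / 24),
                     c(0.007, 1, 7, 28))
  bol <- simulate_pk(p, dose_events(0, 9), c(0.007, 1, 7, 28))
  # after the short infusion ends the profiles converge
  expect_equal(inf$cfree[2:4], bol$cfree[2:4], tolerance = 5e-3)
  # mid-infusion only a third of the dose is in: much lower than bolus
  expect_lt(inf$cfree[1], 0.5 * bol$cfree[1])
})

test_that("terminal half-life follows the disposition eigenvalue", {
  # frozen eigenvalue-oracle value for the published typical parameters
  A <- matrix(c(-(0.0187 + 0.127) / 0.141, 0.127 / 0.127,
                0.127 / 0.141, -0.127 / 0.127), 2, 2, byrow = TRUE)
  lz <- min(abs(eigen(A)$values))
  expect_equal(terminal_halflife(0.0187, 0.141, 0.127, 0.127),
               log(2) / lz, tolerance = 1e-10)
  expect_equal(terminal_halflife(0.0187, 0.141, 0.127, 0.127), 10.274,
               tolerance = 1e-4)
  # one-compartment limit
  expect_equal(terminal_halflife(0.0187, 0.141, 0, 0.127),
               log(2) * 0.141 / 0.0187, tolerance = 1e-10)
  # scaling CL and volumes together leaves the half-life unchanged
  expect_equal(terminal_halflife(0.0187 * 3, 0.141 * 3, 0.127 * 3,
                                 0.127 * 3),
               terminal_halflife(0.0187, 0.141, 0.127, 0.127))
})

test_that("target-mediated elimination dominates only at low levels", {
  p <- monkey_pk_typical()
  # instantaneous effective clearance = linear CL + binding flux / C:
  # more than doubled at 0.4 ug/mL, marginal at 50 ug/mL
  eff_cl <- function(cfree) {
    # choose cen so that the QSS free concentration equals cfree
    rtot <- p$KSYN / p$KDEG
    cen <- (cfree + rtot * cfree / (p$KSS + cfree)) * p$VC
    d <- pk_rhs(c(0, cen, cfree * p$VP, rtot), p)
    -unname(d[2]) / cfree  # total elimination flux per unit conc
  }
  expect_gt(eff_cl(0.4), 2 * p$CL)
  expect_lt(eff_cl(50), 1.2 * p$CL)
  # AUC(0-inf) dose-proportionality is approached at high doses and
  # markedly violated around the saturation window
  times <- seq(0.01, 300, by = 0.5)
  auc_of <- function(dose) {
    s <- simulate_pk(p, dose_events(0, dose), times)
    auc_trapezoid(s$time, s$cfree)
  }
  expect_equal(auc_of(120) / auc_of(60), 2, tolerance = 0.02)
  expect_gt(auc_of(1.8) / auc_of(0.9), 2.1)
})
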