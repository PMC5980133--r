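# a tight residual spec for noise-free self-consistency fits: the
# log-variance term of the Gaussian likelihood then has negligible pull
tight_resid <- function()
  residual_spec(pk_add_var = 1e-10, pk_prop_var = 1e-6,
                pd_prop = c(NK = 1e-6, B = 1e-6, T = 1e-6))

test_that("the pooled -2 log-likelihood matches per-point arithmetic", {
  rs <- residual_spec()
  # zero residual: contribution is the normalising constant only
  f <- 2.5
  expect_equal(neg2_loglik(f, f, "PK", rs),
               log(2 * pi * (3.17e-4 + 0.0677 * f^2)))
  # three-point toy set against spreadsheet-style summation
  y <- c(1.2, 0.8, 3.0); f3 <- c(1.0, 1.0, 2.5)
  s2 <- 3.17e-4 + 0.0677 * f3^2
  expect_equal(neg2_loglik(y, f3, "PK", rs),
               sum(log(2 * pi * s2) + (y - f3)^2 / s2),
               tolerance = 1e-10)
  # PD is proportional-only
  s2pd <- 0.2905 * f3^2
  expect_equal(neg2_loglik(y, f3, "NK", rs),
               sum(log(2 * pi * s2pd) + (y - f3)^2 / s2pd),
               tolerance = 1e-10)
  # scaling all variances by 4 adds 2 N log 2 when residuals vanish
  rs4 <- residual_spec(pk_add_var = 4 * 3.17e-4,
                       pk_prop_var = 4 * 0.0677)
  expect_equal(neg2_loglik(f3, f3, "PK", rs4) -
                 neg2_loglik(f3, f3, "PK", rs),
               2 * 3 * log(2), tolerance = 1e-10)
  # zero prediction under proportional-only error is guarded
  expect_error(neg2_loglik(1, 0, "NK", rs), "variance")
})

make_rich_pk <- function(seed = 1, n = 1) {
  des <- study_design("rich",
    arms = list(list(dose_mgkg = 3, n = n, route = "IV_BOLUS",
                     label = "3")),
    schedule = 0,
    pk_times = c(0.021, 0.083, 0.25, 0.5, 1, 2, 3, 5, 7, 10, 14, 21,
                 28, 42),
    pd_times = 0)
  simulate_trial(des, pd = NULL, bsv_pk = NULL, residual = NULL,
                 seed = seed)
}

test_that("noise-free rich data returns the generating PK parameters", {
  tr <- make_rich_pk()
  init <- monkey_pk_typical()
  init$CL <- 0.03; init$VC <- 0.2; init$Q <- 0.08; init$VP <- 0.3
  fit <- fit_pk(tr$data, init = init, residual = tight_resid())
  expect_equal(fit$estimates$CL, 0.0187, tolerance = 1e-3)
  expect_equal(fit$estimates$VC, 0.141, tolerance = 1e-3)
  expect_equal(fit$estimates$Q, 0.127, tolerance = 0.01)
  expect_equal(fit$estimates$VP, 0.127, tolerance = 0.01)
  # the fixed mask is honoured exactly
  for (nm in fit$fixed) expect_identical(fit$estimates[[nm]],
                                         init[[nm]])
  expect_equal(fit$n_obs, 14)
})

test_that("estimates are invariant to observation ordering", {
  tr <- make_rich_pk()
  ds <- tr$data
  set.seed(4)
  shuffled <- ds[sample(nrow(ds)), ]
  class(shuffled) <- class(ds)
  init <- monkey_pk_typical(); init$CL <- 0.025
  f1 <- fit_pk(ds, init = init, free = "CL", residual = tight_resid())
  f2 <- fit_pk(shuffled, init = init, free = "CL",
               residual = tight_resid())
  expect_equal(f1$estimates$CL, f2$estimates$CL, tolerance = 1e-8)
})

test_that("a grossly mis-specified start reaches the same optimum", {
  tr <- make_rich_pk()
  init_lo <- monkey_pk_typical()
  init_hi <- monkey_pk_typical()
  init_hi$CL <- init_hi$CL * 10; init_hi$VC <- init_hi$VC * 10
  f_lo <- fit_pk(tr$data, init = init_lo, free = c("CL", "VC"),
                 residual = tight_resid())
  f_hi <- fit_pk(tr$data, init = init_hi, free = c("CL", "VC"),
                 residual = tight_resid())
  expect_equal(f_hi$estimates$CL, f_lo$estimates$CL, tolerance = 1e-3)
  expect_equal(f_hi$estimates$VC, f_lo$estimates$VC, tolerance = 1e-3)
})

test_that("noise-free T-cell data identifies C50 and EMAX exactly", {
  des <- study_design("t3",
    arms = list(list(dose_mgkg = 0.3, n = 1, route = "IV_BOLUS",
                     label = "a"),
                list(dose_mgkg = 3, n = 1, route = "IV_BOLUS",
                     label = "b"),
                list(dose_mgkg = 30, n = 1, route = "IV_BOLUS",
                     label = "c")),
    schedule = 0, pk_times = 1,
    pd_times = c(0, 1, 2, 5, 7, 14, 28))
  tr <- simulate_trial(des, pd = list(T = pd_typical("T")),
                       bsv_pk = NULL, bsv_pd = NULL, residual = NULL,
                       seed = 3)
  init <- pd_params("T", C50 = 3, EMAX = 0.2, BL = 3732)
  fit <- fit_pd(tr$data, "T", init = init, residual = tight_resid())
  expect_equal(fit$estimates$C50, 11.86, tolerance = 5e-3)
  expect_equal(fit$estimates$EMAX, 0.4656, tolerance = 5e-3)
})

test_that("two-stage mode summarises per-subject fits by the median", {
  tr <- make_rich_pk(seed = 6, n = 3)
  init <- monkey_pk_typical(); init$CL <- 0.03
  fit <- fit_pk(tr$data, init = init, free = c("CL", "VC"),
                mode = "two-stage", residual = tight_resid())
  expect_s3_class(fit, "fit_result")
  expect_equal(nrow(fit$individual), 3)
  expect_equal(fit$estimates$CL, median(fit$individual$CL))
  # all subjects share the typical model here: medians hit the truth
  expect_equal(fit$estimates$CL, 0.0187, tolerance = 2e-3)
})

test_that("Laplace mode handles between-subject variability", {
  des <- study_design("lap",
    arms = list(list(dose_mgkg = 3, n = 6, route = "IV_BOLUS",
                     label = "3")),
    schedule = 0,
    pk_times = c(0.05, 0.5, 2, 7, 14, 28, 42), pd_times = 0)
  tr <- simulate_trial(des, pd = NULL,
                       bsv_pk = bsv_spec(c(CL = 0.4)), seed = 12)
  init <- monkey_pk_typical(); init$CL <- 0.03
  fit <- fit_pk(tr$data, init = init, free = "CL", mode = "laplace",
                bsv = bsv_spec(c(CL = 0.4)),
                control = list(polish = FALSE, restarts = 0,
                               reltol = 1e-6))
  expect_true(is.finite(fit$objective))
  expect_equal(fit$estimates$CL, 0.0187, tolerance = 0.35)
})

test_that("C50 is ill-determined from a floor-dose-only NK design", {
  mk_design <- function(arms) study_design("ident", arms = arms,
    schedule = 0, pk_times = 1,
    pd_times = c(0, 0.5, 1, 2, 3, 5, 7, 10, 14, 21, 28))
  arm <- function(d, n) list(dose_mgkg = d, n = n, route = "IV_BOLUS",
                             label = paste(d))
  low <- simulate_trial(mk_design(list(arm(0.03, 6))),
                        pd = list(NK = pd_typical("NK")),
                        bsv_pk = NULL, residual = NULL, seed = 14)
  multi <- simulate_trial(mk_design(list(arm(0.1, 2), arm(1, 2),
                                         arm(30, 2))),
                          pd = list(NK = pd_typical("NK")),
                          bsv_pk = NULL, residual = NULL, seed = 14)
  # likelihood-slice confidence width for C50 around the generating
  # values: the floor-dose design leaves C50 several-fold less
  # determined than the multi-dose design
  dobj <- function(tr, c50) {
    tot <- 0
    for (p in lymphodep:::.fit_payload(tr$data, "NK")) {
      grid <- sort(unique(c(seq(0, 28, by = 0.05), p$times)))
      prof <- simulate_pk(monkey_pk_typical(), p$doses, grid)
      pdp <- pd_typical("NK"); pdp$C50 <- c50; pdp$BL <- p$bl
      f <- pd_simulate(pdp, prof, p$times)$count
      tot <- tot + neg2_loglik(p$y, pmax(f, 1e-6), "NK",
                               tight_resid())
    }
    tot
  }
  ci_width <- function(tr) {
    g0 <- dobj(tr, 27.5)
    up <- uniroot(function(lc) dobj(tr, exp(lc)) - g0 - 3.84,
                  c(log(27.5), log(27.5) + 6))$root
    lo <- uniroot(function(lc) dobj(tr, exp(lc)) - g0 - 3.84,
                  c(log(27.5) - 6, log(27.5)))$root
    up - lo
  }
  expect_gt(ci_width(low) / ci_width(multi), 3)
})
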