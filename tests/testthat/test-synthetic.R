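test_that("lognormal calibration reproduces printed summaries", {
  # frozen plug-in arithmetic, verified by quantile back-calculation
  fit <- lognormal_from_median_iqr(685, 482.8, 970.1)
  expect_equal(fit$meanlog, log(685))
  expect_equal(fit$meanlog, 6.5294, tolerance = 1e-4)
  expect_equal(fit$sdlog, (log(970.1) - log(482.8)) / (2 * qnorm(0.75)))
  expect_equal(fit$sdlog, 0.51727, tolerance = 1e-4)
  expect_equal(qlnorm(0.5, fit$meanlog, fit$sdlog), 685)
  # unit lognormal
  u <- lognormal_from_median_iqr(1, exp(-qnorm(0.75)), exp(qnorm(0.75)))
  expect_equal(u$meanlog, 0)
  expect_equal(u$sdlog, 1)
  # log-symmetric IQR: exact quartile recovery by Monte Carlo
  set.seed(10)
  g <- lognormal_from_median_iqr(100, 50, 200)
  x <- rlnorm(1e6, g$meanlog, g$sdlog)
  q <- quantile(x, c(0.25, 0.5, 0.75))
  expect_equal(unname(q), c(50, 100, 200), tolerance = 0.01)
  expect_error(lognormal_from_median_iqr(10, 20, 30), "q1 < median")
})

test_that("baseline sampler matches the published population", {
  b <- sample_baselines(1e4, seed = 77)
  expect_equal(median(b$BL_NK), 685, tolerance = 0.02)
  expect_equal(median(b$BL_B), 1279, tolerance = 0.02)
  expect_equal(median(b$BL_T), 3732, tolerance = 0.02)
  # CD38+ fractions: truncated-normal mean correction is below 0.01
  expect_equal(mean(b$CD38_NK), 0.867, tolerance = 0.012)
  expect_true(all(b$CD38_NK >= 0 & b$CD38_NK <= 1))
  expect_true(all(b$CD38_B >= 0 & b$CD38_B <= 1))
  # single draw is reproducible
  expect_identical(sample_baselines(1, seed = 5),
                   sample_baselines(1, seed = 5))
  # quantile convergence ~ n^(-1/2): the large-n median error is smaller
  set.seed(31)
  err <- function(n) abs(median(sample_baselines(n)$BL_NK) - 685)
  e_small <- median(replicate(20, err(100)))
  e_big <- median(replicate(20, err(10000)))
  expect_lt(e_big, e_small)
})

test_that("ADA flags are monotone step functions of onset", {
  # forced onset: simple step
  expect_equal(unclass(generate_ada_flags(c(7, 35, 70), onset = 28)),
               c(FALSE, TRUE, TRUE), ignore_attr = TRUE)
  # zero hazard: never flagged
  f0 <- generate_ada_flags(seq(0, 180, by = 7),
                           ada_config(p_ever = 0), seed = 1)
  expect_false(any(f0))
  # monotone within subject for random onsets
  set.seed(8)
  for (i in 1:50) {
    fl <- generate_ada_flags(sort(runif(12, 0, 120)), ada_config())
    expect_true(all(diff(fl) >= 0))
  }
  # seroconversion fraction close to the configured probability
  set.seed(9)
  hits <- replicate(1000, any(generate_ada_flags(seq(0, 91, by = 7),
                                                 ada_config())))
  se <- sqrt(0.3 * 0.7 / 1000)
  expect_lt(abs(mean(hits) - 0.3), 3 * se)
})

test_that("study templates match the published trial summaries", {
  des <- study_designs()
  expect_named(des, as.character(1:8))
  n_animals <- vapply(des, function(d)
    sum(vapply(d$arms, `[[`, numeric(1), "n")), numeric(1))
  expect_equal(unname(n_animals), c(6, 9, 12, 40, 52, 20, 12, 24))
  counts <- vapply(des, function(d)
    c(length(d$pk_times), length(d$pd_times)), numeric(2))
  expect_equal(unname(counts[1, ]),
               c(19, 14, 15, 28, 31, 31, 16, 19))  # PK samples
  expect_equal(unname(counts[2, ]),
               c(10, 9, 8, 17, 9, 10, 16, 19))     # PD samples
  # study 2: placebo, 0.3 and 3 mg/kg
  expect_setequal(vapply(des[["2"]]$arms, function(a)
    max(a$doses$dose_mgkg), numeric(1)), c(0, 0.3, 3))
  # routes: infusion in studies 1-4, bolus in 5-8, SC arms in 7 and 8
  expect_true(all(vapply(des[["3"]]$arms, `[[`, character(1),
                         "route") == "IV_INFUSION"))
  expect_true(any(vapply(des[["8"]]$arms, `[[`, character(1),
                         "route") == "SC"))
  expect_equal(des[["1"]]$lloq, 0.061)
  expect_equal(des[["5"]]$lloq, 0.05)
})

test_that("generated study datasets are valid, flagged and reproducible", {
  tr <- generate_study_dataset(2, pd = list(NK = pd_typical("NK"),
                                            B = pd_typical("B"),
                                            T = pd_typical("T")),
                               seed = 19)
  expect_equal(length(unique(tr$data$ID)), 9)
  f <- withr::local_tempfile(fileext = ".csv")
  write_dataset(tr$data, f)
  ds <- read_dataset(f)  # passes validation
  expect_s3_class(ds, "monkey_dataset")

  # byte-identical regeneration under the same seed
  tr2 <- generate_study_dataset(2, pd = list(NK = pd_typical("NK"),
                                             B = pd_typical("B"),
                                             T = pd_typical("T")),
                                seed = 19)
  expect_identical(tr$data, tr2$data)

  # placebo PD rows fluctuate about baseline with no trend
  plc <- ds[ds$OBS_TYPE == "NK" & is.na(ds$AMT), ]
  plc <- plc[plc$ID %in% ds$ID[!is.na(ds$AMT)] == FALSE, ]
  ratio <- plc$DV / plc$BL
  expect_gt(cor(ratio, plc$TIME, method = "spearman"), -0.4)
  expect_lt(cor(ratio, plc$TIME, method = "spearman"), 0.4)
})

test_that("early PD samples are flagged and their exclusion spares predose", {
  tr <- generate_study_dataset(8, pd = list(NK = pd_typical("NK")),
                               seed = 23)
  ds <- tr$data
  early <- ds[ds$EARLY == 1 & is.na(ds$AMT), ]
  expect_gt(nrow(early), 0)
  # all early flags sit within 8 h after the dose
  expect_true(all(early$TIME > 0 & early$TIME <= 8 / 24))
  # predose PD samples (time 0) are never excluded by the early filter
  res <- exclude_flagged(ds)
  is_pd <- function(d) is.na(d$AMT) & d$OBS_TYPE %in% c("NK", "B", "T")
  predose <- res$retained[res$retained$TIME == 0 & is_pd(res$retained), ]
  expect_equal(nrow(predose), nrow(ds[ds$TIME == 0 & is_pd(ds), ]))
  # ADA flags, when present, are monotone within subject
  for (sid in unique(ds$ID)) {
    fl <- ds$ADA[ds$ID == sid & ds$OBS_TYPE == "PK"]
    if (length(fl)) expect_true(all(diff(fl) >= 0))
  }
})

test_that("repeated-dose studies accumulate ADA flags, single-dose few", {
  long_tr <- generate_study_dataset(5, pd = NULL, seed = 31)
  short_tr <- generate_study_dataset(2, pd = NULL, seed = 31)
  frac <- function(tr) {
    pk <- tr$data[tr$data$OBS_TYPE == "PK", ]
    mean(pk$ADA)
  }
  expect_gt(frac(long_tr), frac(short_tr))
})
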