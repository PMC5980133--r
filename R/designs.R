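#' Construct a trial design
#'
#' A design holds the dose arms and sampling schedules that drive trial
#' simulation. Each arm specifies its number of animals, route, and a
#' per-occasion dose table in mg/kg (actual amounts are computed from each
#' animal's body weight at simulation time). A dose level of 0 denotes a
#' placebo arm (no dose events, no PK sampling).
#'
#' @param name short identifier.
#' @param arms list of arms; each a list with elements `label`, `n`
#'   (animals), `route` (`"IV_BOLUS"`, `"IV_INFUSION"`, `"SC"`), and
#'   either `dose_mgkg` (single level, given at every `schedule` time) or
#'   `doses` (a `data.frame(time, dose_mgkg)` for per-occasion levels).
#' @param schedule default administration times (days) for arms that give
#'   a single `dose_mgkg`.
#' @param pk_times,pd_times sampling times (days), sorted, non-negative;
#'   time 0 entries are predose samples.
#' @param infusion_duration infusion length (days) for `IV_INFUSION` arms.
#' @param lloq assay lower limit of quantification (ug/mL).
#' @return An object of class `study_design`.
#' @seealso [study_designs()], [simulate_trial()]
#' @export
study_design <- function(name, arms, schedule = 0, pk_times, pd_times,
                         infusion_duration = 0, lloq = 0.05) {
  stopifnot(length(arms) >= 1)
  if (is.unsorted(pk_times) || is.unsorted(pd_times) ||
      any(c(pk_times, pd_times) < 0))
    stop("sampling times must be sorted and non-negative", call. = FALSE)
  arms <- lapply(arms, function(a) {
    if (is.null(a$doses)) {
      stopifnot(!is.null(a$dose_mgkg))
      a$doses <- data.frame(time = schedule, dose_mgkg = a$dose_mgkg)
    }
    if (any(a$doses$dose_mgkg < 0))
      stop("dose levels must be non-negative", call. = FALSE)
    a$route <- match.arg(a$route, c("IV_BOLUS", "IV_INFUSION", "SC"))
    stopifnot(a$n >= 1)
    if (is.null(a$label))
      a$label <- paste0(max(a$doses$dose_mgkg), " mg/kg ", a$route)
    a
  })
  structure(list(name = name, arms = arms, pk_times = pk_times,
                 pd_times = pd_times,
                 infusion_duration = infusion_duration, lloq = lloq),
            class = "study_design")
}

.arm <- function(dose, n, route, label = NULL, doses = NULL)
  list(dose_mgkg = dose, n = n, route = route, label = label,
       doses = doses)

#' Parameter-recovery simulation-study designs
#'
#' Design templates for the package's simulation-based parameter-recovery
#' experiments. All dose on day 1 after a short predose run-in (samples
#' on days 0, 0.5 and 1) so that the recorded baseline is an average of
#' three predose measurements:
#' \describe{
#'   \item{pk}{40 animals, single 3 mg/kg IV bolus, 15 PK samples over
#'     the following 42 days.}
#'   \item{b}{30 animals split over 0.3/3/30 mg/kg IV bolus given
#'     weekly for 13 weeks; B-cell sampling is dense over the first week
#'     (the published studies did the same) and weekly thereafter. The
#'     first-dose transient is what identifies the transit time: with
#'     only weekly samples the nadir delay falls between samples and a
#'     zero-delay model becomes likelihood-equivalent.}
#'   \item{nk}{30 animals split over 0.1/1/30 mg/kg IV bolus, dense NK
#'     sampling over the 28 days after dosing.}
#' }
#'
#' @param type `"pk"`, `"b"` or `"nk"`.
#' @return A [study_design()].
#' @export
recovery_design <- function(type = c("pk", "b", "nk")) {
  type <- match.arg(type)
  switch(type,
    pk = study_design("pkrec",
      arms = list(.arm(3, 40, "IV_BOLUS")), schedule = 1,
      pk_times = 1 + c(0.021, 0.083, 0.25, 0.5, 1, 2, 3, 4, 5, 7, 10,
                       14, 21, 28, 42),
      pd_times = 0),
    b = study_design("brec",
      arms = list(.arm(0.3, 10, "IV_BOLUS"), .arm(3, 10, "IV_BOLUS"),
                  .arm(30, 10, "IV_BOLUS")),
      schedule = seq(1, 85, by = 7),
      pk_times = 2,
      pd_times = c(0, 0.5, 1, 2, 3, 5, seq(8, 92, by = 7))),
    nk = study_design("nkrec",
      arms = list(.arm(0.1, 10, "IV_BOLUS"), .arm(1, 10, "IV_BOLUS"),
                  .arm(30, 10, "IV_BOLUS")),
      schedule = 1,
      pk_times = 2,
      pd_times = c(0, 0.5, 1, 1 + c(0.5, 1, 2, 3, 5, 7, 10, 14, 17, 21,
                                    24, 28))))
}

#' The eight monkey study templates
#'
#' Design templates reproducing the eight preclinical monkey studies:
#' their animal numbers, dose levels (mg/kg), routes (30-minute IV
#' infusion in studies 1-4, IV bolus in studies 5-8, SC arms in studies 7
#' and 8), dosing frequency (single dose, weekly, or every other week) and
#' per-animal PK/PD sample counts (19/10, 14/9, 15/8, 28/17, 31/9, 31/10,
#' 16/16, 19/19). Only those counts and dose levels are published; the
#' sampling clock times themselves are plausible schedules constructed to
#' match the counts. Study 1 used 0.061 ug/mL as the assay quantification
#' limit, all others 0.05.
#'
#' @return Named list of eight [study_design()] objects (`"1"` ... `"8"`).
#' @export
study_designs <- function() {
  inf30 <- 30 / 60 / 24  # 30-min infusion, days
  qw13 <- seq(0, 84, by = 7)
  list(
    "1" = study_design("1",
      arms = list(
        .arm(0, 2, "IV_INFUSION", "placebo"),
        .arm(NULL, 4, "IV_INFUSION", "1+2 mg/kg IV",
             doses = data.frame(time = c(0, 28), dose_mgkg = c(1, 2)))),
      pk_times = c(0, 0.042, 0.25, 1, 2, 4, 7, 10, 14, 21, 28, 28.042,
                   28.25, 29, 30, 32, 35, 42, 56),
      pd_times = c(0, 1, 2, 7, 14, 28, 29, 35, 42, 56),
      infusion_duration = inf30, lloq = 0.061),
    "2" = study_design("2",
      arms = list(.arm(0, 3, "IV_INFUSION", "placebo"),
                  .arm(0.3, 3, "IV_INFUSION"),
                  .arm(3, 3, "IV_INFUSION")),
      schedule = 0,
      pk_times = c(0, 0.021, 0.083, 0.25, 1, 2, 3, 5, 7, 10, 14, 21, 28,
                   42),
      pd_times = c(0, 1, 2, 3, 7, 14, 21, 28, 42),
      infusion_duration = inf30),
    "3" = study_design("3",
      arms = list(.arm(0, 3, "IV_INFUSION", "placebo"),
                  .arm(1, 3, "IV_INFUSION"),
                  .arm(30, 3, "IV_INFUSION"),
                  .arm(100, 3, "IV_INFUSION")),
      schedule = seq(0, 21, by = 7),
      pk_times = c(0, 0.021, 0.25, 1, 2, 7, 7.25, 14, 14.25, 21, 21.25,
                   22, 24, 28, 35),
      pd_times = c(0, 1, 7, 14, 21, 22, 28, 35),
      infusion_duration = inf30),
    "4" = study_design("4",
      arms = list(.arm(0, 10, "IV_INFUSION", "placebo"),
                  .arm(3, 10, "IV_INFUSION"),
                  .arm(30, 10, "IV_INFUSION"),
                  .arm(80, 10, "IV_INFUSION")),
      schedule = seq(0, 84, by = 14),
      pk_times = c(0, 0.021, 0.25, 1, 2, 7, 14, 14.25, 15, 28, 28.25, 42,
                   42.25, 56, 56.25, 70, 70.25, 84, 84.021, 84.25, 85, 86,
                   91, 98, 112, 126, 154, 182),
      pd_times = c(0, 1, 7, 14, 15, 28, 35, 42, 56, 70, 84, 85, 91, 98,
                   112, 140, 182),
      infusion_duration = inf30),
    "5" = study_design("5",
      arms = list(.arm(0, 13, "IV_BOLUS", "placebo"),
                  .arm(0.1, 13, "IV_BOLUS"),
                  .arm(0.3, 13, "IV_BOLUS"),
                  .arm(1, 13, "IV_BOLUS")),
      schedule = qw13,
      pk_times = c(0, 0.01, 0.083, 0.25, 0.5, 1, 2, 3, 5, 7, 14, 21, 28,
                   35, 42, 49, 56, 63, 70, 77, 84, 84.01, 84.25, 85, 86,
                   87, 89, 91, 98, 112, 126),
      pd_times = c(0, 1, 7, 28, 56, 84, 85, 91, 112)),
    "6" = study_design("6",
      arms = list(.arm(0, 10, "IV_BOLUS", "placebo"),
                  .arm(0.1, 10, "IV_BOLUS")),
      schedule = qw13,
      pk_times = c(0, 0.01, 0.083, 0.25, 0.5, 1, 2, 3, 5, 7, 14, 21, 28,
                   35, 42, 49, 56, 63, 70, 77, 84, 84.01, 84.25, 85, 86,
                   87, 89, 91, 98, 112, 126),
      pd_times = c(0, 1, 7, 28, 56, 84, 85, 91, 112, 126)),
    "7" = study_design("7",
      arms = list(.arm(0.1, 3, "IV_BOLUS"),
                  .arm(0.3, 3, "IV_BOLUS"),
                  .arm(1, 3, "IV_BOLUS"),
                  .arm(1, 3, "SC", "1 mg/kg SC")),
      schedule = 0,
      pk_times = c(0, 0.01, 0.083, 0.25, 0.5, 1, 2, 3, 5, 7, 10, 14, 21,
                   28, 42, 56),
      pd_times = c(0, 0.25, 1, 2, 3, 5, 7, 10, 14, 21, 28, 35, 42, 49,
                   56, 57)),
    "8" = study_design("8",
      arms = list(.arm(0.03, 4, "IV_BOLUS"),
                  .arm(0.1, 4, "IV_BOLUS"),
                  .arm(0.3, 4, "IV_BOLUS"),
                  .arm(0.03, 4, "SC", "0.03 mg/kg SC"),
                  .arm(0.1, 4, "SC", "0.1 mg/kg SC"),
                  .arm(0.3, 4, "SC", "0.3 mg/kg SC")),
      schedule = 0,
      pk_times = c(0, 0.01, 0.083, 0.25, 0.5, 1, 2, 3, 4, 5, 7, 10, 14,
                   17, 21, 28, 35, 42, 56),
      pd_times = c(0, 0.01, 0.083, 0.25, 0.5, 1, 2, 3, 4, 5, 7, 10, 14,
                   17, 21, 28, 35, 42, 56)))
}
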