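#' Draw individual parameter sets
#'
#' Applies the diagonal lognormal between-subject variability model
#' `PAR_i = TVPAR * exp(eta_i)`, `eta_i ~ N(0, omega^2)`, to a typical
#' parameter object. Parameters not listed in the BSV spec are left at
#' their typical value, so the population median of each individualised
#' parameter equals the typical value.
#'
#' @param typical a [pk_params()] or [pd_params()] object.
#' @param bsv a [bsv_spec()]; `NULL` means no variability.
#' @param n number of individuals.
#' @param seed optional integer seed (`NULL` uses the current RNG state).
#' @param convention `"cv"` takes omega equal to the CV (the reporting
#'   convention of the published tables); `"log_sd"` uses
#'   `omega = sqrt(log(1 + CV^2))`.
#' @return A list of `n` parameter objects, each carrying its `eta` draws
#'   as attribute `"etas"`.
#' @export
draw_individual_params <- function(typical, bsv = NULL, n = 1,
                                   seed = NULL,
                                   convention = c("cv", "log_sd")) {
  convention <- match.arg(convention)
  if (!is.null(seed)) set.seed(seed)
  cvs <- if (is.null(bsv)) numeric(0) else bsv$cv_by_param
  cvs <- cvs[cvs > 0]
  unknown <- setdiff(names(cvs), names(typical))
  if (length(unknown))
    stop("BSV given for unknown parameter(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  omega <- if (convention == "cv") cvs else sqrt(log(1 + cvs^2))
  lapply(seq_len(n), function(i) {
    p <- typical
    etas <- stats::rnorm(length(omega), 0, omega)
    names(etas) <- names(omega)
    for (nm in names(etas)) p[[nm]] <- p[[nm]] * exp(etas[[nm]])
    attr(p, "etas") <- etas
    p
  })
}

#' Add residual observation error to model predictions
#'
#' PK observations receive combined error `y = f*(1 + eps_p) + eps_a`
#' with `Var(eps_p)` and `Var(eps_a)` from the residual spec; PD cell
#' counts receive proportional error only, `y = f*(1 + eps_p)`. Negative
#' draws are floored at zero; the number of floored values is attached as
#' attribute `"n_floored"`.
#'
#' @param prediction model predictions (>= 0); vectorised.
#' @param observable `"PK"`, `"NK"`, `"B"` or `"T"`.
#' @param residual a [residual_spec()].
#' @param seed optional integer seed.
#' @return Noisy observations, same length as `prediction`.
#' @export
add_residual_error <- function(prediction, observable, residual,
                               seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  observable <- match.arg(observable, c("PK", "NK", "B", "T"))
  stopifnot(all(prediction >= 0))
  n <- length(prediction)
  if (observable == "PK") {
    y <- prediction * (1 + stats::rnorm(n, 0, sqrt(residual$pk_prop_var))) +
      stats::rnorm(n, 0, sqrt(residual$pk_add_var))
  } else {
    sd_p <- sqrt(residual$pd_prop_var[[observable]])
    y <- prediction * (1 + stats::rnorm(n, 0, sd_p))
  }
  floored <- y < 0
  y[floored] <- 0
  attr(y, "n_floored") <- sum(floored)
  y
}

#' Simulate a whole monkey trial
#'
#' Builds a population of animals for a [study_design()] (body weights
#' uniform on 2.1-4.7 kg, per-animal baselines, lognormal BSV on PK and
#' PD parameters), computes each animal's dose amounts from its dose
#' level and predose body weight, simulates concentration and cell-count
#' trajectories, applies residual error and the quantification-limit
#' flag, and assembles the dataset in the [read_dataset()] dialect. The
#' recorded `BL` column is the mean of the animal's observed predose
#' measurements of that cell type. The whole simulation is a pure
#' function of (design, parameters, seed).
#'
#' Placebo animals contribute PD rows only (their counts fluctuate about
#' baseline through the residual model); treated animals contribute dose,
#' PK and PD rows. Observations scheduled at a dose time are predose.
#'
#' @param design a [study_design()].
#' @param pk typical [pk_params()].
#' @param pd named list of typical [pd_params()] objects (any subset of
#'   `NK`, `B`, `T`); `NULL` simulates PK only.
#' @param bsv_pk,bsv_pd [bsv_spec()] for PK and (named list, per cell
#'   type) PD parameters; `NULL` disables BSV. A `BL` entry in a PD spec
#'   is applied to the animal's baseline when no `baseline` sampler is
#'   supplied.
#' @param residual a [residual_spec()]; `NULL` disables residual error.
#' @param baseline a [baseline_spec()] population sampler for true
#'   baselines, or `NULL` to use the typical `BL` (with `BL` BSV if
#'   specified).
#' @param seed integer seed.
#' @param convention BSV convention, see [draw_individual_params()].
#' @return An object of class `simulated_trial`: list with `subjects`
#'   (data.frame), `data` (the `monkey_dataset`), `design` and `seed`.
#' @export
simulate_trial <- function(design, pk = monkey_pk_typical(), pd = NULL,
                           bsv_pk = NULL, bsv_pd = NULL,
                           residual = residual_spec(),
                           baseline = NULL, seed = 1,
                           convention = c("cv", "log_sd")) {
  convention <- match.arg(convention)
  stopifnot(inherits(design, "study_design"))
  set.seed(seed)
  rows <- list()
  subjects <- list()
  id <- 0
  for (a in design$arms) {
    for (j in seq_len(a$n)) {
      id <- id + 1
      sid <- sprintf("%s-%03d", design$name, id)
      bw <- stats::runif(1, 2.1, 4.7)
      sex <- if (j %% 2) "F" else "M"
      treated <- any(a$doses$dose_mgkg > 0)
      # individual PK parameters
      pk_i <- draw_individual_params(pk, bsv_pk, 1,
                                     convention = convention)[[1]]
      pk_i$VC <- apply_route_covariate(pk_i$VC, a$route, pk_i$THETA_ROUT)
      # true baselines
      bl_true <- .subject_baselines(pd, baseline, bsv_pd, convention)
      # individual PD parameters
      pd_i <- lapply(names(pd), function(ct) {
        spec <- if (!is.null(bsv_pd)) bsv_pd[[ct]] else NULL
        if (!is.null(spec)) {
          keep <- setdiff(names(spec$cv_by_param), "BL")
          spec <- bsv_spec(spec$cv_by_param[keep])
        }
        p <- draw_individual_params(pd[[ct]], spec, 1,
                                    convention = convention)[[1]]
        p$BL <- bl_true[[ct]]
        p
      })
      names(pd_i) <- names(pd)

      dd <- a$doses[a$doses$dose_mgkg > 0, , drop = FALSE]
      doses <- if (treated)
        dose_events(dd$time, dd$dose_mgkg * bw, a$route,
                    if (a$route == "IV_INFUSION")
                      design$infusion_duration else 0)
      else NULL
      first_dose <- if (treated) min(doses$time) else 0

      sub_rows <- list()
      if (treated) {
        sub_rows$dose <- data.frame(
          ID = sid, TIME = doses$time, AMT = doses$amount,
          DUR = doses$duration, ROUTE = doses$route, DV = NA_real_,
          OBS_TYPE = ".", BL = NA_real_, ADA = 0L, BLQ = 0L, EARLY = 0L,
          BW = bw, SEX = sex, stringsAsFactors = FALSE)
        # PK profile on a grid dense enough to drive the PD models
        grid <- sort(unique(c(.conc_grid(doses$time,
                                         max(design$pk_times,
                                             design$pd_times)),
                              design$pk_times, design$pd_times)))
        prof <- simulate_pk(pk_i, doses, grid, rtol = 1e-8, atol = 1e-10)
        f_pk <- prof$cfree[match(design$pk_times, prof$time)]
        y_pk <- if (is.null(residual)) f_pk else
          add_residual_error(f_pk, "PK", residual)
        sub_rows$pk <- data.frame(
          ID = sid, TIME = design$pk_times, AMT = NA_real_, DUR = NA_real_,
          ROUTE = a$route, DV = as.numeric(y_pk), OBS_TYPE = "PK",
          BL = NA_real_, ADA = 0L,
          BLQ = as.integer(y_pk < design$lloq), EARLY = 0L,
          BW = bw, SEX = sex, stringsAsFactors = FALSE)
        conc <- prof
      } else {
        conc <- function(t) rep(0, length(t))
      }

      for (ct in names(pd)) {
        f_pd <- pd_simulate(pd_i[[ct]], conc, design$pd_times)$count
        y_pd <- if (is.null(residual)) f_pd else
          add_residual_error(f_pd, ct, residual)
        predose <- design$pd_times <= first_dose
        blcol <- mean(y_pd[predose])
        # degenerate predose record (no predose samples, or all floored
        # to zero): fall back to the latent baseline
        if (!any(predose) || !is.finite(blcol) || blcol <= 0)
          blcol <- bl_true[[ct]]
        early <- .early_flag(design$pd_times, if (treated) doses$time
                             else numeric(0))
        sub_rows[[ct]] <- data.frame(
          ID = sid, TIME = design$pd_times, AMT = NA_real_,
          DUR = NA_real_, ROUTE = a$route, DV = as.numeric(y_pd),
          OBS_TYPE = ct, BL = blcol, ADA = 0L, BLQ = 0L,
          EARLY = as.integer(early), BW = bw, SEX = sex,
          stringsAsFactors = FALSE)
      }
      if (length(sub_rows)) {
        sub <- do.call(rbind, sub_rows)
        sub <- sub[order(sub$TIME,
                         match(sub$OBS_TYPE,
                               c(".", "PK", "NK", "B", "T"))), ]
        rows[[sid]] <- sub
      }
      subjects[[sid]] <- data.frame(
        ID = sid, arm = a$label, dose_mgkg = max(a$doses$dose_mgkg),
        route = a$route, BW = bw, SEX = sex,
        BL_NK = bl_true[["NK"]] %||% NA_real_,
        BL_B = bl_true[["B"]] %||% NA_real_,
        BL_T = bl_true[["T"]] %||% NA_real_,
        stringsAsFactors = FALSE)
    }
  }
  ds <- do.call(rbind, rows)
  rownames(ds) <- NULL
  class(ds) <- c("monkey_dataset", "data.frame")
  structure(list(subjects = do.call(rbind, c(subjects,
                                             make.row.names = FALSE)),
                 data = ds, design = design, seed = seed),
            class = "simulated_trial")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.subject_baselines <- function(pd, baseline, bsv_pd, convention) {
  out <- list()
  for (ct in names(pd)) {
    if (!is.null(baseline) && ct %in% names(baseline$cells)) {
      out[[ct]] <- .sample_baseline_one(baseline, ct)
    } else {
      cv <- 0
      if (!is.null(bsv_pd) && !is.null(bsv_pd[[ct]])) {
        v <- bsv_pd[[ct]]$cv_by_param
        if ("BL" %in% names(v)) cv <- v[["BL"]]
      }
      omega <- if (convention == "cv") cv else sqrt(log(1 + cv^2))
      out[[ct]] <- pd[[ct]]$BL * exp(stats::rnorm(1, 0, omega))
    }
  }
  out
}

.early_flag <- function(times, dose_times) {
  if (!length(dose_times)) return(rep(FALSE, length(times)))
  vapply(times, function(t) {
    any(t > dose_times & t - dose_times <= 8 / 24)
  }, logical(1))
}

#' @export
print.simulated_trial <- function(x, ...) {
  cat("<simulated_trial> study", x$design$name, "-",
      nrow(x$subjects), "animals,", nrow(x$data), "rows (seed",
      paste0(x$seed, ")"), "\n")
  invisible(x)
}
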