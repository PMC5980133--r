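#' Pooled -2 log-likelihood of observations given predictions
#'
#' Gaussian observation model matching the residual-error structure: for
#' each observation, `log(2*pi*sigma2(f)) + (y - f)^2 / sigma2(f)` with
#' `sigma2(f) = add + prop * f^2` for PK and `sigma2(f) = prop * f^2` for
#' cell counts; the value is the sum over observations.
#'
#' @param y observed values.
#' @param f model predictions (same length).
#' @param observable `"PK"`, `"NK"`, `"B"` or `"T"`.
#' @param residual a [residual_spec()].
#' @return The -2 log-likelihood (scalar).
#' @export
neg2_loglik <- function(y, f, observable, residual) {
  observable <- match.arg(observable, c("PK", "NK", "B", "T"))
  s2 <- .residual_var(f, observable, residual)
  if (any(s2 <= 0))
    stop("non-positive predicted variance (zero prediction with ",
         "proportional-only error?)", call. = FALSE)
  sum(log(2 * pi * s2) + (y - f)^2 / s2)
}

# ---- parameter transforms -------------------------------------------------

.pk_log_params <- c("KA", "CL", "VC", "Q", "VP", "KINT", "KSS", "KSYN",
                    "KDEG")

.to_trans <- function(params, free, type = "pk") {
  vapply(free, function(nm) {
    v <- params[[nm]]
    if (type == "pd" && params$cell_type == "T" && nm == "EMAX")
      stats::qlogis(v)
    else if (nm %in% c("F_logit", "THETA_ROUT")) v
    else log(v)
  }, numeric(1))
}

.from_trans <- function(params, theta, type = "pk") {
  for (nm in names(theta)) {
    params[[nm]] <-
      if (type == "pd" && params$cell_type == "T" && nm == "EMAX")
        stats::plogis(theta[[nm]])
      else if (nm %in% c("F_logit", "THETA_ROUT")) theta[[nm]]
      else exp(theta[[nm]])
  }
  params
}

# ---- dataset preparation --------------------------------------------------

# per-subject fitting payloads; applies the standard exclusions
.fit_payload <- function(ds, observable, drop_ada = TRUE,
                         drop_blq = TRUE, drop_early_pd = TRUE) {
  ds <- exclude_flagged(ds, drop_ada, drop_blq, drop_early_pd)$retained
  subs <- split_subjects(ds)
  out <- lapply(names(subs), function(sid) {
    s <- subs[[sid]]
    obs <- s$obs[s$obs$OBS_TYPE == observable & !is.na(s$obs$DV), ,
                 drop = FALSE]
    if (!nrow(obs)) return(NULL)
    obs <- obs[order(obs$TIME), , drop = FALSE]
    if (observable != "PK" && nrow(s$doses)) {
      # predose cell counts enter the model only through the BL column
      # (their average); keeping them as observations too would anchor
      # the fit on residuals that are zero by construction
      obs <- obs[obs$TIME > min(s$doses$time), , drop = FALSE]
      if (!nrow(obs)) return(NULL)
    }
    list(id = sid, doses = s$doses, times = obs$TIME, y = obs$DV,
         bl = if (observable != "PK") obs$BL[1] else NA_real_,
         route = if (nrow(s$doses)) s$doses$route[1] else "IV_BOLUS")
  })
  out[!vapply(out, is.null, logical(1))]
}

# ---- optimiser ------------------------------------------------------------

.minimise <- function(obj, start, control = list()) {
  maxit <- control$maxit %||% 500
  reltol <- control$reltol %||% 1e-8
  restarts <- control$restarts %||% 2
  if (length(start) == 1) {
    o <- stats::optimize(function(x) obj(stats::setNames(x,
                                                         names(start))),
                         interval = start + c(-log(200), log(200)),
                         tol = 1e-9)
    fit <- list(par = stats::setNames(o$minimum, names(start)),
                value = o$objective, convergence = 0L)
    restarts <- 0
  } else
  fit <- stats::optim(start, obj, method = "Nelder-Mead",
                      control = list(maxit = maxit, reltol = reltol))
  # re-inflate the simplex at the solution; cheap insurance against
  # premature collapse of the Nelder-Mead polytope
  for (r in seq_len(restarts)) {
    again <- stats::optim(fit$par, obj, method = "Nelder-Mead",
                          control = list(maxit = maxit,
                                         reltol = reltol))
    if (again$value >= fit$value - abs(fit$value) * 1e-10) {
      fit <- if (again$value < fit$value) again else fit
      break
    }
    fit <- again
  }
  if (isTRUE(control$polish %||% TRUE)) {
    pol <- try(stats::nlminb(fit$par, obj,
                             control = list(iter.max = 30)),
               silent = TRUE)
    if (!inherits(pol, "try-error") && is.finite(pol$objective) &&
        pol$objective <= fit$value) {
      fit$par <- pol$par
      fit$value <- pol$objective
      fit$convergence <- pol$convergence
    }
  }
  fit
}

.fit_result <- function(params, theta, objective, convergence, mode,
                        free, fixed, n_obs, se = NULL,
                        individual = NULL) {
  structure(list(estimates = params, theta = theta,
                 objective = objective, convergence = convergence,
                 mode = mode, free = free, fixed = fixed, n_obs = n_obs,
                 se_pct = se, individual = individual),
            class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat("<fit_result> mode:", x$mode, "| -2LL:", signif(x$objective, 8),
      "| n_obs:", x$n_obs, "| convergence:", x$convergence, "\n")
  est <- unlist(x$estimates[x$free])
  if (!is.null(x$se_pct)) {
    print(data.frame(estimate = signif(est, 4),
                     pct_se = signif(x$se_pct[x$free], 3)))
  } else print(signif(est, 4))
  if (length(x$fixed)) cat("fixed:", paste(x$fixed, collapse = ", "), "\n")
  invisible(x)
}

# finite-difference %SE on the transformed scale (log-scale SE is a
# relative SE, reported in percent to mirror the published tables)
.pct_se <- function(obj, theta) {
  H <- try(stats::optimHess(theta, obj), silent = TRUE)
  if (inherits(H, "try-error")) return(NULL)
  V <- try(solve(H / 2), silent = TRUE)  # -2LL Hessian -> 2 * information
  if (inherits(V, "try-error") || any(diag(V) <= 0)) return(NULL)
  100 * sqrt(diag(V))
}

#' Fit the population PK model
#'
#' Estimates selected PK parameters from a dataset by maximum likelihood
#' under the combined residual-error model, with all other parameters
#' held fixed (mirroring the staged strategy in which the target-binding
#' block is estimated on low-dose data and then frozen). Three modes:
#' \describe{
#'   \item{pooled}{one naive-pooled fit of typical values to all
#'     subjects' data.}
#'   \item{two-stage}{independent per-subject fits; the reported
#'     estimates are the medians of the individual estimates (the median
#'     of a lognormal individual parameter is its typical value).}
#'   \item{laplace}{marginal likelihood with lognormal random effects on
#'     the parameters listed in `bsv` (diagonal omega, held fixed at the
#'     supplied CVs), integrated out by the Laplace approximation.}
#' }
#' Observations flagged ADA or below the quantification limit are
#' excluded before fitting. Positive parameters are optimised on the log
#' scale, bioavailability on the logit scale.
#'
#' @param ds a `monkey_dataset`.
#' @param init initial/fixed [pk_params()] values.
#' @param free names of parameters to estimate (default disposition
#'   block `CL`, `VC`, `Q`, `VP`).
#' @param mode estimation mode.
#' @param residual a [residual_spec()] (known, not estimated).
#' @param bsv a [bsv_spec()]; required for `mode = "laplace"`.
#' @param se logical: compute finite-difference %SE (pooled mode).
#' @param rtol,atol solver tolerances used during fitting.
#' @param control optimiser control (`maxit`, `reltol`, `polish`).
#' @return A `fit_result`.
#' @export
fit_pk <- function(ds, init = monkey_pk_typical(),
                   free = c("CL", "VC", "Q", "VP"),
                   mode = c("pooled", "two-stage", "laplace"),
                   residual = residual_spec(), bsv = NULL, se = FALSE,
                   rtol = 1e-6, atol = 1e-8, control = list()) {
  mode <- match.arg(mode)
  stopifnot(all(free %in% names(init)))
  payload <- .fit_payload(ds, "PK")
  if (!length(payload)) stop("no usable PK observations", call. = FALSE)
  n_obs <- sum(vapply(payload, function(p) length(p$y), numeric(1)))
  tmdd_free <- any(c("KINT", "KSS", "KSYN", "KDEG") %in% free)
  doses_all <- unlist(lapply(payload, function(p) p$doses$amount))
  if (tmdd_free && length(doses_all) && min(doses_all) >= 1 * 2.1)
    warning("all doses lie in a range with little target-mediated ",
            "information; TMDD parameters may not be identifiable")

  predict_one <- function(p, params) {
    pi <- params
    pi$VC <- apply_route_covariate(params$VC, p$route,
                                   params$THETA_ROUT)
    simulate_pk(pi, p$doses, p$times, rtol = rtol, atol = atol)$cfree
  }
  obj_pooled <- function(theta, subset = payload) {
    params <- .from_trans(init, theta)
    tot <- 0
    for (p in subset) {
      f <- try(predict_one(p, params), silent = TRUE)
      if (inherits(f, "try-error") || any(!is.finite(f)))
        return(1e10)
      tot <- tot + neg2_loglik(p$y, f, "PK", residual)
    }
    tot
  }
  start <- .to_trans(init, free)

  if (mode == "pooled") {
    fit <- .minimise(obj_pooled, start, control)
    params <- .from_trans(init, fit$par)
    ses <- if (se) .pct_se(obj_pooled, fit$par) else NULL
    if (!is.null(ses)) names(ses) <- free
    return(.fit_result(params, fit$par, fit$value, fit$convergence,
                       mode, free, setdiff(names(init), free), n_obs,
                       se = ses))
  }
  if (mode == "two-stage") {
    ind <- lapply(payload, function(p) {
      fit <- .minimise(function(th) obj_pooled(th, list(p)), start,
                       control)
      c(unlist(.from_trans(init, fit$par)[free]), .obj = fit$value,
        .conv = fit$convergence)
    })
    ind <- do.call(rbind, ind)
    rownames(ind) <- vapply(payload, `[[`, character(1), "id")
    med <- apply(ind[, free, drop = FALSE], 2, stats::median)
    params <- init
    for (nm in free) params[[nm]] <- med[[nm]]
    return(.fit_result(params, .to_trans(params, free),
                       sum(ind[, ".obj"]), max(ind[, ".conv"]), mode,
                       free, setdiff(names(init), free), n_obs,
                       individual = as.data.frame(ind)))
  }
  # laplace
  if (is.null(bsv) || !length(bsv$cv_by_param))
    stop("mode = 'laplace' requires a bsv_spec", call. = FALSE)
  obj <- .laplace_objective(payload, init, free, bsv, residual,
                            function(p, params) predict_one(p, params),
                            "PK")
  fit <- .minimise(obj, start, control)
  params <- .from_trans(init, fit$par)
  .fit_result(params, fit$par, fit$value, fit$convergence, mode, free,
              setdiff(names(init), free), n_obs)
}

# Laplace marginal -2LL with diagonal omega fixed at the supplied CVs
.laplace_objective <- function(payload, init, free, bsv, residual,
                               predictor, observable) {
  omega <- bsv$cv_by_param[bsv$cv_by_param > 0]
  enames <- names(omega)
  function(theta) {
    params <- .from_trans(init, theta,
                          if (observable == "PK") "pk" else "pd")
    tot <- 0
    for (p in payload) {
      g <- function(eta) {
        pi <- params
        for (k in seq_along(enames))
          pi[[enames[k]]] <- params[[enames[k]]] * exp(eta[k])
        f <- try(predictor(p, pi), silent = TRUE)
        if (inherits(f, "try-error") || any(!is.finite(f)))
          return(1e10)
        neg2_loglik(p$y, f, observable, residual) +
          sum(eta^2 / omega^2) + sum(log(2 * pi_const * omega^2))
      }
      inner <- stats::nlminb(rep(0, length(enames)), g,
                             control = list(iter.max = 50))
      H <- try(stats::optimHess(inner$par, function(e) 0.5 * g(e)),
               silent = TRUE)
      ld <- if (inherits(H, "try-error")) 0 else {
        dh <- determinant(as.matrix(H), logarithm = TRUE)
        if (dh$sign > 0) as.numeric(dh$modulus) else 0
      }
      tot <- tot + inner$objective + ld -
        length(enames) * log(2 * pi_const)
    }
    tot
  }
}
pi_const <- base::pi

#' Fit a lymphocyte-depletion model with the PK model frozen
#'
#' Sequential PK-then-PD estimation: each subject's concentration
#' time-course is computed once from the supplied (fixed) PK parameters
#' and that subject's dosing records, then the structural PD parameters
#' are estimated under the proportional residual-error model. Individual
#' baselines are taken from the dataset's `BL` column, and `KOUT` of the
#' NK turnover model is tied to them through `KOUT = KIN/BL`. PD samples
#' within 8 hours of a dose are excluded, as are ADA-affected samples.
#' Modes as in [fit_pk()].
#'
#' The recorded `BL` column is a noisy average of predose measurements;
#' treating it as the animal's exact baseline biases the pooled
#' structural estimates. By default the fit therefore profiles out one
#' multiplicative baseline factor per animal — the closed-form maximiser
#' of the proportional-error likelihood given the current structural
#' parameters — mirroring the baseline random effect of the published
#' analysis (`baseline_scale = FALSE` disables this).
#'
#' @param ds a `monkey_dataset`.
#' @param cell_type `"NK"`, `"B"` or `"T"`.
#' @param pk_params fixed [pk_params()] (IV typical; the route covariate
#'   is applied per subject).
#' @param init initial [pd_params()] for the cell type (its `BL` is
#'   ignored in favour of the per-subject data column).
#' @param free parameters to estimate (defaults: NK `KIN`, `C50`,
#'   `EMAX`; B `MTT`, `C50`, `EMAX`; T `C50`, `EMAX`).
#' @param mode,residual,bsv,se,control as in [fit_pk()].
#' @param baseline_scale profile a per-animal baseline multiplier
#'   (default `TRUE`; applies to the pooled and two-stage modes, not to
#'   Laplace).
#' @param rtol,atol PD solver tolerances used during fitting.
#' @return A `fit_result`.
#' @export
fit_pd <- function(ds, cell_type, pk_params = monkey_pk_typical(),
                   init = pd_typical(cell_type), free = NULL,
                   mode = c("pooled", "two-stage", "laplace"),
                   residual = residual_spec(), bsv = NULL, se = FALSE,
                   baseline_scale = TRUE,
                   rtol = 1e-6, atol = 1e-6, control = list()) {
  mode <- match.arg(mode)
  cell_type <- match.arg(cell_type, c("NK", "B", "T"))
  if (is.null(free))
    free <- switch(cell_type, NK = c("KIN", "C50", "EMAX"),
                   B = c("MTT", "C50", "EMAX"), T = c("C50", "EMAX"))
  payload <- .fit_payload(ds, cell_type)
  if (!length(payload)) stop("no usable PD observations", call. = FALSE)
  bad_bl <- vapply(payload, function(p) !is.finite(p$bl) || p$bl <= 0,
                   logical(1))
  if (any(bad_bl))
    stop("non-positive baseline (BL) for subject(s): ",
         paste(vapply(payload[bad_bl], `[[`, character(1), "id"),
               collapse = ", "), call. = FALSE)
  n_obs <- sum(vapply(payload, function(p) length(p$y), numeric(1)))

  # fixed-PK concentration profiles, one per subject
  for (i in seq_along(payload)) {
    p <- payload[[i]]
    if (nrow(p$doses)) {
      pk_i <- pk_params
      pk_i$VC <- apply_route_covariate(pk_params$VC, p$route,
                                       pk_params$THETA_ROUT)
      grid <- sort(unique(c(.conc_grid(p$doses$time, max(p$times, 1)),
                            p$times)))
      prof <- simulate_pk(pk_i, p$doses, grid)
      payload[[i]]$conc <- prof[, c("time", "cfree")]
    } else {
      payload[[i]]$conc <- data.frame(time = c(0, max(p$times, 1)),
                                      cfree = c(0, 0))
    }
  }

  prop_var <- residual$pd_prop_var[[cell_type]]
  # the BL column averages the predose samples; its log-scale error SD
  # for a three-sample average under the proportional error model
  scale_sd <- sqrt(prop_var / 3)
  predict_one <- function(p, params) {
    params$BL <- p$bl
    # floor far below any real count so the proportional variance stays
    # positive when a trajectory touches zero
    pmax(pd_simulate(params, p$conc, p$times, rtol = rtol,
                     atol = atol)$count, 1e-6)
  }
  subject_neg2ll <- function(p, params) {
    g <- predict_one(p, params)
    if (!baseline_scale || prop_var <= 0)
      return(neg2_loglik(p$y, g, cell_type, residual))
    # penalised profile over one multiplicative baseline factor s:
    # -2 log lik of y | s*g plus the log-normal penalty for s implied
    # by the predose-average error (shrinks s toward 1)
    r <- p$y / g
    n <- length(r); m1 <- mean(r); m2 <- mean(r * r)
    base <- n * log(2 * pi * prop_var) + 2 * sum(log(g))
    h <- function(ls) {
      s <- exp(ls)
      base + 2 * n * ls +
        n * (m2 - 2 * m1 * s + s * s) / (prop_var * s * s) +
        ls * ls / scale_sd^2
    }
    stats::optimize(h, c(-1.5, 1.5), tol = 1e-8)$objective
  }
  obj_pooled <- function(theta, subset = payload) {
    params <- .from_trans(init, theta, "pd")
    tot <- 0
    for (p in subset) {
      f <- try(subject_neg2ll(p, params), silent = TRUE)
      if (inherits(f, "try-error") || !is.finite(f))
        return(1e10)
      tot <- tot + f
    }
    tot
  }
  start <- .to_trans(init, free, "pd")

  if (mode == "pooled") {
    fit <- .minimise(obj_pooled, start, control)
    params <- .from_trans(init, fit$par, "pd")
    ses <- if (se) .pct_se(obj_pooled, fit$par) else NULL
    if (!is.null(ses)) names(ses) <- free
    return(.fit_result(params, fit$par, fit$value, fit$convergence,
                       mode, free, setdiff(c("KIN", "MTT", "C50",
                                             "EMAX"), free), n_obs,
                       se = ses))
  }
  if (mode == "two-stage") {
    ind <- lapply(payload, function(p) {
      fit <- .minimise(function(th) obj_pooled(th, list(p)), start,
                       control)
      c(unlist(.from_trans(init, fit$par, "pd")[free]),
        .obj = fit$value, .conv = fit$convergence)
    })
    ind <- do.call(rbind, ind)
    rownames(ind) <- vapply(payload, `[[`, character(1), "id")
    med <- apply(ind[, free, drop = FALSE], 2, stats::median)
    params <- init
    for (nm in free) params[[nm]] <- med[[nm]]
    return(.fit_result(params, .to_trans(params, free, "pd"),
                       sum(ind[, ".obj"]), max(ind[, ".conv"]), mode,
                       free, setdiff(c("KIN", "MTT", "C50", "EMAX"),
                                     free), n_obs,
                       individual = as.data.frame(ind)))
  }
  if (is.null(bsv) || !length(bsv$cv_by_param))
    stop("mode = 'laplace' requires a bsv_spec", call. = FALSE)
  obj <- .laplace_objective(payload, init, free, bsv, residual,
                            predict_one, cell_type)
  fit <- .minimise(obj, start, control)
  params <- .from_trans(init, fit$par, "pd")
  .fit_result(params, fit$par, fit$value, fit$convergence, mode, free,
              setdiff(c("KIN", "MTT", "C50", "EMAX"), free), n_obs)
}
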