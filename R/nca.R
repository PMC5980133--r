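#' Area under the curve by the trapezoidal rule
#'
#' Default method is linear-up/log-down: intervals where the
#' concentration rises (or touches zero) use the linear trapezoid,
#' falling intervals use the log trapezoid
#' `(c1 - c2) * dt / log(c1/c2)`, which is exact for mono-exponential
#' decline.
#'
#' @param times strictly increasing sampling times (days).
#' @param concs concentrations (>= 0), same length.
#' @param method `"linlog"` (linear-up/log-down) or `"linear"`.
#' @return AUC from the first to the last sample (ug*day/mL).
#' @export
auc_trapezoid <- function(times, concs, method = c("linlog", "linear")) {
  method <- match.arg(method)
  if (length(times) < 2) stop("need at least two points", call. = FALSE)
  if (any(diff(times) <= 0))
    stop("times must be strictly increasing", call. = FALSE)
  if (any(concs < 0)) stop("concentrations must be >= 0", call. = FALSE)
  c1 <- concs[-length(concs)]; c2 <- concs[-1]; dt <- diff(times)
  lin <- (c1 + c2) / 2 * dt
  if (method == "linear") return(sum(lin))
  logdown <- c2 < c1 & c2 > 0
  lin[logdown] <- (c1[logdown] - c2[logdown]) * dt[logdown] /
    log(c1[logdown] / c2[logdown])
  sum(lin)
}

#' Fit the terminal elimination rate constant
#'
#' Log-linear regression over candidate terminal windows: all windows
#' ending at the last quantifiable point and spanning between
#' `min_points` and `n_last` of the final quantifiable samples. The
#' window with the best adjusted R-squared wins (ties go to more
#' points). Returns `NULL` when no admissible window with a negative
#' slope exists.
#'
#' @param times,concs the profile; only points with `concs > lloq` are
#'   used.
#' @param lloq quantification limit (points at or below are dropped).
#' @param min_points minimum window size (>= 3).
#' @param n_last number of trailing quantifiable points considered.
#' @return List with `lambda_z` (1/day), `t_half` (days), `intercept`
#'   (log scale), `n_points`, `adj_r2`, `window` (time range), or `NULL`.
#' @export
lambda_z_fit <- function(times, concs, lloq = 0, min_points = 3,
                         n_last = 6) {
  keep <- concs > lloq
  t <- times[keep]; c <- concs[keep]
  n <- length(t)
  if (n < min_points) return(NULL)
  best <- NULL
  for (k in min_points:min(n_last, n)) {
    idx <- (n - k + 1):n
    x <- t[idx]; ly <- log(c[idx])
    sxx <- sum((x - mean(x))^2)
    slope <- sum((x - mean(x)) * (ly - mean(ly))) / sxx
    if (!is.finite(slope) || slope >= 0) next
    icpt <- mean(ly) - slope * mean(x)
    ssres <- sum((ly - icpt - slope * x)^2)
    sstot <- sum((ly - mean(ly))^2)
    # adjusted R^2; an (essentially) exact fit counts as 1
    r2adj <- if (ssres <= 1e-12 * max(sstot, 1)) 1
    else 1 - (ssres / sstot) * (k - 1) / (k - 2)
    if (is.null(best) || r2adj > best$adj_r2 + 1e-10 ||
        (abs(r2adj - best$adj_r2) <= 1e-10 && k > best$n_points)) {
      best <- list(lambda_z = -slope, t_half = log(2) / -slope,
                   intercept = icpt, n_points = k, adj_r2 = r2adj,
                   window = range(x))
    }
  }
  best
}

#' Noncompartmental analysis of one concentration profile
#'
#' Computes the standard single-dose NCA quantities: Cmax, Tmax,
#' AUC(0-last) by linear-up/log-down, lambda_z by best-window log-linear
#' regression, terminal half-life, AUC(0-inf) = AUC(0-last) +
#' Clast/lambda_z, clearance `CL = dose/AUC_inf` (apparent CL/F for SC
#' profiles) and terminal volume `Vz = CL/lambda_z`. Per-kg values are
#' added when a body weight is supplied.
#'
#' @param times,concs the observed profile (days, ug/mL).
#' @param dose administered dose (mg).
#' @param body_weight optional body weight (kg) for per-kg scaling.
#' @param lloq quantification limit passed to [lambda_z_fit()].
#' @return One-row `data.frame` with columns `Cmax`, `Tmax`, `AUC_last`,
#'   `AUC_inf`, `lambda_z`, `t_half`, `CL`, `Vz` (and `CL_mL_kg_day`,
#'   `Vz_mL_kg` when weight is given); lambda_z-dependent fields are `NA`
#'   when no terminal fit is admissible.
#' @export
nca_summary <- function(times, concs, dose, body_weight = NULL,
                        lloq = 0) {
  stopifnot(dose > 0)
  auc_last <- auc_trapezoid(times, concs)
  imax <- which.max(concs)
  lz <- lambda_z_fit(times, concs, lloq = lloq)
  if (is.null(lz)) {
    auc_inf <- lambda_z <- t_half <- CL <- Vz <- NA_real_
  } else {
    clast <- concs[max(which(concs > lloq))]
    lambda_z <- lz$lambda_z
    t_half <- lz$t_half
    auc_inf <- auc_last + clast / lambda_z
    CL <- dose / auc_inf
    Vz <- CL / lambda_z
  }
  out <- data.frame(Cmax = max(concs), Tmax = times[imax],
                    AUC_last = auc_last, AUC_inf = auc_inf,
                    lambda_z = lambda_z, t_half = t_half, CL = CL,
                    Vz = Vz)
  if (!is.null(body_weight)) {
    out$CL_mL_kg_day <- CL * 1000 / body_weight
    out$Vz_mL_kg <- Vz * 1000 / body_weight
  }
  out
}

#' Per-subject NCA over a dataset
#'
#' Applies [nca_summary()] to the quantifiable PK observations of each
#' dosed subject of a dataset (single-dose designs; the profile after the
#' first dose is used).
#'
#' @param ds a `monkey_dataset`.
#' @param lloq quantification limit (ug/mL).
#' @return `data.frame` with one row per evaluable subject.
#' @export
nca_dataset <- function(ds, lloq = 0.05) {
  subs <- split_subjects(ds)
  rows <- lapply(names(subs), function(sid) {
    s <- subs[[sid]]
    if (!nrow(s$doses)) return(NULL)
    pk <- s$obs[s$obs$OBS_TYPE == "PK" & !is.na(s$obs$DV), , drop = FALSE]
    pk <- pk[pk$TIME > min(s$doses$time), , drop = FALSE]
    pk <- pk[pk$DV > lloq, , drop = FALSE]
    if (nrow(pk) < 3) return(NULL)
    cbind(ID = sid,
          nca_summary(pk$TIME, pk$DV, dose = s$doses$amount[1],
                      body_weight = s$bw, lloq = lloq))
  })
  do.call(rbind, rows)
}
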