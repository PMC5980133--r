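#' Fixed-effect pharmacokinetic parameters
#'
#' Container for the structural PK parameters of the two-compartment
#' QSS-TMDD model: first-order absorption from a subcutaneous depot,
#' linear clearance from the central compartment, linear exchange with a
#' peripheral compartment, and quasi-steady-state binding to a turning-over
#' target pool in the central compartment. Defaults are the published
#' population typical values for the monkey.
#'
#' Bioavailability is parameterised on the logit scale (`F_logit`) so that
#' the derived fraction absorbed lies strictly in (0, 1); use
#' [bioavailability()] to recover the fraction. `THETA_ROUT` is the
#' proportional covariate effect of the subcutaneous route on `VC`
#' (see [apply_route_covariate()]).
#'
#' @param F_logit logit-scale bioavailability parameter (unitless). The
#'   default corresponds to F = 0.227.
#' @param KA first-order absorption rate from the SC depot (1/day).
#' @param CL linear clearance (L/day).
#' @param VC central volume of distribution (L), IV typical value.
#' @param Q intercompartmental clearance (L/day).
#' @param VP peripheral volume of distribution (L).
#' @param KINT elimination (internalisation) rate of the drug-target
#'   complex (1/day).
#' @param KSS quasi-steady-state constant (ug/mL). Dimensioned as a
#'   concentration: KSS = (KOFF + KINT)/KON.
#' @param KSYN zero-order target synthesis rate (target units/L per day).
#' @param KDEG first-order target degradation rate (1/day).
#' @param THETA_ROUT proportional effect of the SC route on `VC`
#'   (unitless; must satisfy 1 + THETA_ROUT > 0).
#' @return An object of class `pk_params` (named list).
#' @seealso [monkey_pk_typical()], [simulate_pk()]
#' @examples
#' p <- pk_params()
#' bioavailability(p$F_logit)
#' @export
pk_params <- function(F_logit = -1.225386,
                      KA = 0.399,
                      CL = 0.0187,
                      VC = 0.141,
                      Q = 0.127,
                      VP = 0.127,
                      KINT = 0.1,
                      KSS = 5.68,
                      KSYN = 0.04,
                      KDEG = 0.00452,
                      THETA_ROUT = -0.697) {
  p <- list(F_logit = F_logit, KA = KA, CL = CL, VC = VC, Q = Q, VP = VP,
            KINT = KINT, KSS = KSS, KSYN = KSYN, KDEG = KDEG,
            THETA_ROUT = THETA_ROUT)
  for (nm in c("KA", "CL", "VC", "Q", "VP", "KSS")) {
    if (!is.finite(p[[nm]]) || p[[nm]] <= 0)
      stop("pk_params: '", nm, "' must be strictly positive", call. = FALSE)
  }
  for (nm in c("KINT", "KSYN", "KDEG")) {
    if (!is.finite(p[[nm]]) || p[[nm]] < 0)
      stop("pk_params: '", nm, "' must be non-negative", call. = FALSE)
  }
  if (!is.finite(F_logit))
    stop("pk_params: 'F_logit' must be finite", call. = FALSE)
  if (1 + THETA_ROUT <= 0)
    stop("pk_params: route effect must keep (1 + THETA_ROUT) > 0",
         call. = FALSE)
  structure(p, class = "pk_params")
}

#' Published monkey population PK typical values
#'
#' Convenience constructor returning [pk_params()] at its defaults, the
#' final population estimates from the pooled eight-study monkey analysis.
#'
#' @return A `pk_params` object.
#' @export
monkey_pk_typical <- function() pk_params()

#' Bioavailability from its logit-scale parameter
#'
#' The absorbed fraction is modelled as `exp(x)/(1 + exp(x))` so that any
#' real-valued parameter maps to a fraction strictly inside (0, 1).
#'
#' @param F_logit logit-scale parameter (any finite real; vectorised).
#' @return Fraction(s) in (0, 1).
#' @examples
#' bioavailability(0)            # 0.5
#' bioavailability(-1.225386)    # 0.227
#' @export
bioavailability <- function(F_logit) stats::plogis(F_logit)

#' Apply the route-of-administration covariate to the central volume
#'
#' The subcutaneous route acts proportionally on the central volume of
#' distribution: `VC_SC = VC_IV * (1 + THETA_ROUT)`. Intravenous routes
#' leave `VC` unchanged.
#'
#' @param typical_VC central volume for the IV route (L).
#' @param route one of `"IV_BOLUS"`, `"IV_INFUSION"`, `"SC"`.
#' @param THETA_ROUT proportional covariate coefficient.
#' @return Route-adjusted central volume (L).
#' @examples
#' apply_route_covariate(0.141, "SC", -0.697)  # 0.0427 L
#' @export
apply_route_covariate <- function(typical_VC, route, THETA_ROUT) {
  stopifnot(typical_VC > 0)
  route <- match.arg(route, c("IV_BOLUS", "IV_INFUSION", "SC"))
  if (route != "SC") return(typical_VC)
  if (1 + THETA_ROUT <= 0)
    stop("route covariate would make VC non-positive", call. = FALSE)
  typical_VC * (1 + THETA_ROUT)
}

#' Pharmacodynamic structural parameters for one cell type
#'
#' The three depletion models share an Emax-type drug effect
#' `E(c) = EMAX * c^hill / (C50^hill + c^hill)` but differ structurally:
#' \describe{
#'   \item{NK}{turnover (indirect response) model; `KIN` (cells/uL/day) is
#'     the zero-order production rate, the drug stimulates the loss rate;
#'     `KOUT` is tied to the baseline via `KOUT = KIN/BL`; `EMAX` is the
#'     maximal additional depletion rate (1/day).}
#'   \item{B}{four-transit-compartment chain with common rate `4/MTT`
#'     feeding circulating B cells; drug stimulates loss of circulating
#'     cells; `EMAX` is a maximal additional depletion rate (1/day).}
#'   \item{T}{memoryless direct response
#'     `T(c) = BL * (1 - EMAX * c/(c + C50))`; `EMAX` is the maximal
#'     depletable fraction and must lie in [0, 1].}
#' }
#' Hill exponents are fixed at 1 in the final published models; the `hill`
#' argument exists as an off-by-default variant.
#'
#' @param cell_type `"NK"`, `"B"` or `"T"`.
#' @param KIN NK production rate, cells/uL per day (NK only).
#' @param MTT mean transit time, days (B only).
#' @param C50 concentration of half-maximal effect (ug/mL).
#' @param EMAX maximal effect (1/day for NK/B; fraction for T).
#' @param BL baseline cell count (cells/uL).
#' @param hill Hill exponent for the effect function (default 1).
#' @return An object of class `pd_params`.
#' @seealso [pd_typical()], [nk_simulate()], [bcell_simulate()],
#'   [tcell_response()]
#' @export
pd_params <- function(cell_type, KIN = NULL, MTT = NULL, C50, EMAX, BL,
                      hill = 1) {
  cell_type <- match.arg(cell_type, c("NK", "B", "T"))
  if (!is.finite(C50) || C50 <= 0) stop("pd_params: C50 must be > 0",
                                        call. = FALSE)
  if (!is.finite(BL) || BL <= 0) stop("pd_params: BL must be > 0",
                                      call. = FALSE)
  if (hill <= 0) stop("pd_params: hill must be > 0", call. = FALSE)
  if (cell_type == "NK") {
    if (is.null(KIN) || KIN <= 0)
      stop("pd_params: NK model requires KIN > 0", call. = FALSE)
    if (EMAX < 0) stop("pd_params: EMAX must be >= 0", call. = FALSE)
  }
  if (cell_type == "B") {
    if (is.null(MTT) || MTT <= 0)
      stop("pd_params: B model requires MTT > 0", call. = FALSE)
    if (EMAX < 0) stop("pd_params: EMAX must be >= 0", call. = FALSE)
  }
  if (cell_type == "T" && (EMAX < 0 || EMAX > 1))
    stop("pd_params: T-cell EMAX must lie in [0, 1]", call. = FALSE)
  structure(list(cell_type = cell_type, KIN = KIN, MTT = MTT, C50 = C50,
                 EMAX = EMAX, BL = BL, hill = hill),
            class = "pd_params")
}

#' Published monkey PD typical values per cell type
#'
#' Final population typical estimates of the three depletion models, with
#' the population median baseline of each cell type as `BL`.
#'
#' @param cell_type `"NK"`, `"B"` or `"T"`.
#' @return A `pd_params` object.
#' @export
pd_typical <- function(cell_type) {
  cell_type <- match.arg(cell_type, c("NK", "B", "T"))
  switch(cell_type,
    NK = pd_params("NK", KIN = 13957, C50 = 27.5, EMAX = 414.6, BL = 685),
    B  = pd_params("B", MTT = 8.19, C50 = 19.8, EMAX = 2.43, BL = 1279),
    T  = pd_params("T", C50 = 11.86, EMAX = 0.4656, BL = 3732))
}

#' Between-subject variability specification
#'
#' Diagonal lognormal random-effect model: each listed parameter `PAR` is
#' individualised as `PAR_i = PAR * exp(eta_i)` with
#' `eta_i ~ N(0, omega^2)`. The published "% CV" magnitudes are taken as
#' omega directly (the common reporting convention); set
#' `convention = "log_sd"` in the sampling functions for the alternative
#' `omega = sqrt(log(1 + CV^2))`.
#'
#' @param cv_by_param named numeric vector of coefficients of variation as
#'   fractions (e.g. `c(CL = 0.429)`); parameters without BSV are omitted.
#' @return An object of class `bsv_spec`.
#' @seealso [draw_individual_params()]
#' @export
bsv_spec <- function(cv_by_param = numeric(0)) {
  cv_by_param <- unlist(cv_by_param)
  if (length(cv_by_param) && (is.null(names(cv_by_param)) ||
                              any(!nzchar(names(cv_by_param)))))
    stop("bsv_spec: cv_by_param must be a named vector", call. = FALSE)
  if (any(cv_by_param < 0))
    stop("bsv_spec: CVs must be >= 0", call. = FALSE)
  structure(list(cv_by_param = cv_by_param), class = "bsv_spec")
}

#' Published between-subject variability magnitudes
#'
#' PK: KA 42.1%, CL 42.9%, VC 19.8%, VP 39.4%, KINT 49.3%.
#' PD (per cell type): NK KIN 111% / C50 146% / baseline 28.6%;
#' B MTT 135% / baseline 24.03%; T EMAX 69.46% / baseline 29.08%.
#'
#' @param which `"PK"`, `"NK"`, `"B"` or `"T"`.
#' @return A `bsv_spec` object.
#' @export
bsv_typical <- function(which = c("PK", "NK", "B", "T")) {
  which <- match.arg(which)
  switch(which,
    PK = bsv_spec(c(KA = 0.421, CL = 0.429, VC = 0.198, VP = 0.394,
                    KINT = 0.493)),
    NK = bsv_spec(c(KIN = 1.11, C50 = 1.46, BL = 0.286)),
    B  = bsv_spec(c(MTT = 1.35, BL = 0.2403)),
    T  = bsv_spec(c(EMAX = 0.6946, BL = 0.2908)))
}

#' Residual (observation) error specification
#'
#' PK observations carry a combined additive and proportional error,
#' `y = f * (1 + eps_p) + eps_a`; PD cell counts carry a proportional
#' error only, `y = f * (1 + eps_p)`. Magnitudes default to the published
#' estimates and are interpreted as variances (the NONMEM SIGMA
#' convention); set `pd_as_sd = TRUE` to interpret the PD magnitudes as
#' standard deviations instead.
#'
#' @param pk_add_var additive PK variance ((ug/mL)^2).
#' @param pk_prop_var proportional PK variance (unitless).
#' @param pd_prop named vector of per-cell-type proportional PD magnitudes.
#' @param pd_as_sd logical; interpret `pd_prop` as SDs rather than
#'   variances.
#' @return An object of class `residual_spec`.
#' @seealso [add_residual_error()], [neg2_loglik()]
#' @export
residual_spec <- function(pk_add_var = 3.17e-4,
                          pk_prop_var = 0.0677,
                          pd_prop = c(NK = 0.2905, B = 0.136, T = 0.1343),
                          pd_as_sd = FALSE) {
  if (pk_add_var < 0 || pk_prop_var < 0 || any(pd_prop < 0))
    stop("residual_spec: variances must be >= 0", call. = FALSE)
  pd_var <- if (pd_as_sd) pd_prop^2 else pd_prop
  structure(list(pk_add_var = pk_add_var, pk_prop_var = pk_prop_var,
                 pd_prop_var = pd_var), class = "residual_spec")
}

#' @export
print.pk_params <- function(x, ...) {
  cat("<pk_params>  F =", signif(bioavailability(x$F_logit), 3), "\n")
  v <- unlist(x[names(x) != "F_logit"])
  print(signif(v, 4))
  invisible(x)
}

#' @export
print.pd_params <- function(x, ...) {
  cat("<pd_params> cell type:", x$cell_type, "\n")
  v <- unlist(x[!vapply(x, is.null, logical(1)) &
                  !(names(x) %in% "cell_type")])
  print(signif(v, 4))
  invisible(x)
}

# internal: residual variance for a vector of predictions
.residual_var <- function(f, observable, residual) {
  if (observable == "PK") {
    residual$pk_add_var + residual$pk_prop_var * f^2
  } else {
    residual$pd_prop_var[[observable]] * f^2
  }
}
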