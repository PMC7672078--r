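#' Carbon fluxes for a given state
#'
#' Evaluates every transformation flux of the model at one state:
#' Michaelis-Menten DOC uptake with the 1/Yg prefactor, enzyme-catalysed
#' decomposition of the two particulate pools and the mineral-associated
#' pool, Langmuir-style DOC adsorption/desorption, substrate-gated dormancy
#' and reactivation, maintenance and growth respiration, mortality, and
#' enzyme production/turnover.  All rates are Arrhenius-scaled to the
#' temperature in `env` before evaluation.
#'
#' @param state a [pool_state()] (non-negative).
#' @param mp [microbial_params()].
#' @param fp [fixed_params()].
#' @param env [mend_env()].
#' @return Named numeric vector of fluxes, mg C cm^-3 h^-1.
#' @export
compute_fluxes <- function(state, mp, fp, env) {
  y <- .as_state(state)
  if (any(y < 0)) stop("negative pool value")
  pv <- mend_parms_vector(mp, fp, env)
  .mend_fluxes_pv(y, pv)
}

#' @noRd
.mend_fluxes_pv <- function(y, pv) {
  y <- pmax(y, 0)
  S <- y[["D"]] / (pv[["KD"]] + y[["D"]])
  F1 <- (pv[["Vg"]] + pv[["Vmt"]]) * S * y[["BA"]] / pv[["Yg"]]
  F2 <- pv[["VP1"]] * y[["EP1"]] * y[["P1"]] / (pv[["KP1"]] + y[["P1"]])
  F3 <- pv[["VP2"]] * y[["EP2"]] * y[["P2"]] / (pv[["KP2"]] + y[["P2"]])
  F4 <- pv[["VM"]] * y[["EM"]] * y[["M"]] / (pv[["KM"]] + y[["M"]])
  qfrac <- y[["Q"]] / pv[["Qmax"]]
  F5 <- pv[["Kads"]] * y[["D"]] * (1 - qfrac)
  F6 <- pv[["Kdes"]] * qfrac
  F7 <- (1 - S) * pv[["Vmt"]] * y[["BA"]]
  F8 <- S * pv[["Vmt"]] * y[["BD"]]
  c(uptake = F1, dec_P1 = F2, dec_P2 = F3, dec_M = F4,
    adsorption = F5, desorption = F6, dormancy = F7, reactivation = F8,
    growth = pv[["Vg"]] * S * y[["BA"]],
    maint_active = pv[["Vmt"]] * S * y[["BA"]],
    maint_dormant = pv[["beta"]] * pv[["Vmt"]] * y[["BD"]],
    growth_resp = (1 - pv[["Yg"]]) * F1,
    mortality = pv[["rM"]] * y[["BA"]],
    eprod_P1 = pv[["pEP1"]] * y[["BA"]],
    eprod_P2 = pv[["pEP2"]] * y[["BA"]],
    eprod_M = pv[["pEM"]] * y[["BA"]],
    eturn_P1 = pv[["rE"]] * y[["EP1"]],
    eturn_P2 = pv[["rE"]] * y[["EP2"]],
    eturn_M = pv[["rE"]] * y[["EM"]])
}

#' Time derivative of every pool (reference implementation)
#'
#' Pure-R assembly of the mass balance; the compiled RHS used for
#' integration implements the identical equations and is tested against
#' this function.  By construction the derivatives conserve carbon:
#' the sum over all pools plus the CO2 rate equals the total external
#' input exactly.
#'
#' @inheritParams compute_fluxes
#' @return Named numeric vector of derivatives (mg C cm^-3 h^-1), one per
#'   pool plus the CO2 rate.
#' @export
mend_rhs <- function(state, mp, fp, env) {
  y <- .as_state(state)
  if (any(y < 0)) stop("negative pool value")
  pv <- mend_parms_vector(mp, fp, env)
  .mend_rhs_pv(y, pv)
}

#' @noRd
.mend_rhs_pv <- function(y, pv) {
  f <- .mend_fluxes_pv(y, pv)
  eturn <- f[["eturn_P1"]] + f[["eturn_P2"]] + f[["eturn_M"]]
  eprod <- f[["eprod_P1"]] + f[["eprod_P2"]] + f[["eprod_M"]]
  growth_net <- pv[["Yg"]] * f[["uptake"]] - f[["maint_active"]]
  c(P1 = pv[["IP1"]] - f[["dec_P1"]],
    P2 = pv[["IP2"]] + (1 - pv[["gD"]]) * f[["mortality"]] - f[["dec_P2"]],
    M = (1 - pv[["fD"]]) * (f[["dec_P1"]] + f[["dec_P2"]]) - f[["dec_M"]],
    D = pv[["ID"]] + pv[["fD"]] * (f[["dec_P1"]] + f[["dec_P2"]]) +
      f[["dec_M"]] + pv[["gD"]] * f[["mortality"]] + eturn -
      f[["uptake"]] - f[["adsorption"]] + f[["desorption"]],
    Q = f[["adsorption"]] - f[["desorption"]],
    BA = growth_net - f[["mortality"]] - eprod - f[["dormancy"]] +
      f[["reactivation"]],
    BD = f[["dormancy"]] - f[["reactivation"]] - f[["maint_dormant"]],
    EP1 = f[["eprod_P1"]] - f[["eturn_P1"]],
    EP2 = f[["eprod_P2"]] - f[["eturn_P2"]],
    EM = f[["eprod_M"]] - f[["eturn_M"]],
    CO2 = f[["growth_resp"]] + f[["maint_active"]] + f[["maint_dormant"]])
}

#' deSolve-style wrapper around the reference RHS
#' @noRd
.mend_rhs_desolve <- function(t, y, pv) {
  list(.mend_rhs_pv(y, pv))
}
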