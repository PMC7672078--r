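#' @useDynLib mendfusion
#' @importFrom stats qf kruskal.test t.test rnorm runif rlnorm sd median quantile setNames
#' @importFrom utils read.csv write.csv modifyList
NULL

#' Canonical pool ordering of the model state
#'
#' The ten carbon pools plus cumulative CO2, in the order used by every
#' state vector, trajectory column layout and the compiled RHS.
#' @export
MEND_POOLS <- c("P1", "P2", "M", "D", "Q", "BA", "BD", "EP1", "EP2", "EM", "CO2")

#' Gas constant in J mol-1 K-1
#' @noRd
.RGAS <- 8.314

#' Construct a MEND pool state
#'
#' A pool state holds the ten carbon pools of the microbial-enzyme
#' decomposition model plus cumulative respired CO2, all in mg C cm^-3 soil:
#' two particulate pools (`P1` degraded by oxidative enzymes, `P2` by
#' hydrolytic enzymes), mineral-associated carbon `M`, dissolved carbon `D`,
#' mineral-adsorbed dissolved carbon `Q`, active and dormant microbial
#' biomass `BA`/`BD`, and the three enzyme pools `EP1`, `EP2`, `EM`.
#'
#' @param P1,P2,M,D,Q,BA,BD,EP1,EP2,EM,CO2 pool sizes, mg C cm^-3 soil.
#' @return A named numeric vector of class `mend_state`.
#' @export
#' @examples
#' s <- pool_state(P1 = 4, P2 = 4, M = 20, D = 0.1, Q = 0.2, BA = 0.1, BD = 0.3)
#' soc(s); mbc(s)
pool_state <- function(P1 = 0, P2 = 0, M = 0, D = 0, Q = 0, BA = 0, BD = 0,
                       EP1 = 0, EP2 = 0, EM = 0, CO2 = 0) {
  x <- c(P1 = P1, P2 = P2, M = M, D = D, Q = Q, BA = BA, BD = BD,
         EP1 = EP1, EP2 = EP2, EM = EM, CO2 = CO2)
  if (anyNA(x) || any(!is.finite(x))) stop("pool state must be finite")
  if (any(x < 0)) stop("pool state must be non-negative")
  structure(x, class = c("mend_state", "numeric"))
}

.as_state <- function(x) {
  if (length(x) != length(MEND_POOLS)) stop("state must have 11 components")
  x <- as.numeric(x)
  if (anyNA(x) || any(!is.finite(x))) stop("state contains non-finite values")
  names(x) <- MEND_POOLS
  x
}

#' Total soil organic carbon of a state (all pools, mg C cm^-3)
#' @param state a pool state (any named vector with the MEND pools).
#' @export
soc <- function(state) {
  sum(state[setdiff(MEND_POOLS, "CO2")])
}

#' Microbial biomass carbon of a state (active + dormant, mg C cm^-3)
#' @param state a pool state.
#' @export
mbc <- function(state) {
  unname(state["BA"] + state["BD"])
}

#' The five calibrated microbial parameters
#'
#' @param r0 initial active fraction of microbial biomass, in (0, 1].
#' @param Vg maximum specific growth rate, h^-1.
#' @param alpha ratio Vmt / (Vg + Vmt) relating the specific maintenance
#'   rate Vmt to the growth rate; in [0, 1).
#' @param KD half-saturation constant for microbial uptake of dissolved
#'   organic carbon, mg C cm^-3.
#' @param Yg intrinsic carbon use efficiency at the 20 degC reference
#'   temperature, in (0, 1).
#' @return An object of class `microbial_params`.
#' @export
microbial_params <- function(r0, Vg, alpha, KD, Yg) {
  stopifnot(is.numeric(r0), is.numeric(Vg), is.numeric(alpha),
            is.numeric(KD), is.numeric(Yg))
  if (r0 <= 0 || r0 > 1) stop("r0 must be in (0, 1]")
  if (Vg < 0) stop("Vg must be >= 0")
  if (alpha < 0 || alpha >= 1) stop("alpha must be in [0, 1)")
  if (KD <= 0) stop("KD must be > 0")
  if (Yg <= 0 || Yg >= 1) stop("Yg must be in (0, 1)")
  structure(list(r0 = r0, Vg = Vg, alpha = alpha, KD = KD, Yg = Yg),
            class = "microbial_params")
}

#' @export
print.microbial_params <- function(x, ...) {
  cat("Microbial parameters:\n")
  cat(sprintf("  r0 = %.4g  Vg = %.4g h-1  alpha = %.4g  KD = %.4g mg C cm-3  Yg = %.4g\n",
              x$r0, x$Vg, x$alpha, x$KD, x$Yg))
  invisible(x)
}

#' Default microbial parameters
#'
#' The case-averaged best-fit values obtained from multi-year cellulose
#' incubations (r0 = 0.59, Vg = 0.038 h^-1, alpha = 0.27,
#' KD = 0.02 mg C cm^-3, Yg = 0.30); used as the reference parameter set for
#' projections and sensitivity sweeps.
#'
#' @return A `microbial_params` object.
#' @export
microbial_defaults <- function() {
  microbial_params(r0 = 0.59, Vg = 0.038, alpha = 0.27, KD = 0.02, Yg = 0.30)
}

#' Prior bounds for the calibrated microbial parameters
#'
#' @return A 2-row matrix (`lo`, `hi`) with one column per parameter.
#' @export
microbial_bounds <- function() {
  b <- rbind(lo = c(r0 = 0.01, Vg = 0.001, alpha = 0.01, KD = 1e-4, Yg = 0.1),
             hi = c(r0 = 1.00, Vg = 0.200, alpha = 0.60, KD = 0.5,  Yg = 0.7))
  b
}

#' Convert a numeric vector to microbial parameters
#' @noRd
.mp_from_vector <- function(theta) {
  microbial_params(r0 = theta[[1]], Vg = theta[[2]], alpha = theta[[3]],
                   KD = theta[[4]], Yg = theta[[5]])
}

#' Specific maintenance rate implied by Vg and alpha
#'
#' alpha is defined as Vmt / (Vg + Vmt); inverting gives
#' Vmt = alpha * Vg / (1 - alpha).
#'
#' @param Vg maximum specific growth rate, h^-1.
#' @param alpha maintenance ratio in [0, 1).
#' @return Vmt, the maximum specific maintenance rate (h^-1).
#' @export
#' @examples
#' derived_maintenance_rate(0.048, 0.30)
derived_maintenance_rate <- function(Vg, alpha) {
  if (any(alpha < 0) || any(alpha >= 1)) stop("alpha must be in [0, 1)")
  if (any(Vg < 0)) stop("Vg must be >= 0")
  alpha * Vg / (1 - alpha)
}

#' Arrhenius temperature scaling factor
#'
#' Relative change of a rate with activation energy `Ea` when moving from
#' the reference temperature to `T`:
#' `exp((Ea * 1000 / R) * (1/(Tref + 273.15) - 1/(T + 273.15)))`.
#'
#' @param Ea activation energy, kJ mol^-1.
#' @param T temperature, degC.
#' @param Tref reference temperature, degC (default 20).
#' @return Dimensionless positive factor; 1 at `T == Tref`.
#' @export
#' @examples
#' arrhenius_factor(47, T = 25)
arrhenius_factor <- function(Ea, T, Tref = 20) {
  if (any(T <= -273.15) || any(Tref <= -273.15)) {
    stop("temperatures must exceed absolute zero")
  }
  exp((Ea * 1000 / .RGAS) * (1 / (Tref + 273.15) - 1 / (T + 273.15)))
}

#' Temperature-adjusted carbon use efficiency
#'
#' CUE declines linearly with warming at slope `kYg` (degC^-1) from its
#' intrinsic value at the reference temperature; the result is clipped to
#' (0.001, 0.999) purely as a numerical safeguard for the 1/Yg uptake
#' prefactor (the clip is never active in the temperature range of interest).
#'
#' @param Yg_ref intrinsic carbon use efficiency at `Tref`.
#' @param kYg temperature slope, degC^-1 (default -0.01).
#' @param T temperature, degC.
#' @param Tref reference temperature, degC (default 20).
#' @return Carbon use efficiency at `T`.
#' @export
#' @examples
#' yg_at_temperature(0.30, -0.01, T = 25)
yg_at_temperature <- function(Yg_ref, kYg = -0.01, T, Tref = 20) {
  if (any(Yg_ref <= 0) || any(Yg_ref >= 1)) stop("Yg_ref must be in (0, 1)")
  pmin(pmax(Yg_ref + kYg * (T - Tref), 0.001), 0.999)
}

#' Fixed (non-calibrated) model parameters
#'
#' Kinetic and partition constants that are held fixed during calibration.
#' Defaults are read from the versioned `mend_defaults` configuration file
#' shipped with the package; any value can be overridden by name.
#'
#' @param ... named overrides, e.g. `fixed_params(kYg = -0.012)`.
#' @param file alternative configuration file (`key = value` text format).
#' @return An object of class `fixed_params`.
#' @export
#' @examples
#' fp <- fixed_params()
#' fp$kYg
fixed_params <- function(..., file = NULL) {
  if (is.null(file)) {
    file <- system.file("extdata", "mend_defaults.conf", package = "mendfusion")
  }
  defaults <- read_param_config(file)
  over <- list(...)
  if (length(over)) {
    bad <- setdiff(names(over), names(defaults))
    if (length(bad)) stop("unknown fixed parameter(s): ", paste(bad, collapse = ", "))
    defaults[names(over)] <- over
  }
  fp <- defaults
  with(fp, {
    if (any(c(VP1, VP2, VM, KP1, KP2, KM, Kads, Kdes, rM,
              pEP1, pEP2, pEM, rE) < 0)) stop("rates must be >= 0")
    if (fD < 0 || fD > 1 || gD < 0 || gD > 1) stop("fD, gD must be in [0, 1]")
    if (beta < 0 || beta > 1) stop("beta must be in [0, 1]")
    if (Qmax <= 0) stop("Qmax must be > 0")
  })
  structure(fp, class = "fixed_params")
}

#' @export
print.fixed_params <- function(x, ...) {
  cat("Fixed MEND parameters (", length(unclass(x)), " values):\n", sep = "")
  v <- unlist(unclass(x))
  print(v)
  invisible(x)
}

#' Parse a grouped key = value configuration file
#' @noRd
read_param_config <- function(file) {
  if (!file.exists(file)) stop("configuration file not found: ", file)
  lines <- readLines(file, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "[")]
  kv <- strsplit(lines, "=", fixed = TRUE)
  bad <- lengths(kv) != 2
  if (any(bad)) stop("malformed config line(s): ", paste(lines[bad], collapse = "; "))
  vals <- lapply(kv, function(p) {
    v <- suppressWarnings(as.numeric(trimws(p[2])))
    if (is.na(v)) stop("non-numeric config value for key ", trimws(p[1]))
    v
  })
  stats::setNames(vals, vapply(kv, function(p) trimws(p[1]), ""))
}

#' Environmental forcing for a model run
#'
#' @param T soil temperature, degC.
#' @param IP1,IP2,ID external carbon input rates into the two particulate
#'   pools and the dissolved pool, mg C cm^-3 h^-1 (all zero for closed
#'   laboratory incubations).
#' @return An object of class `mend_env`.
#' @export
mend_env <- function(T = 20, IP1 = 0, IP2 = 0, ID = 0) {
  if (any(c(IP1, IP2, ID) < 0)) stop("inputs must be >= 0")
  structure(list(T = T, IP1 = IP1, IP2 = IP2, ID = ID), class = "mend_env")
}

#' Temperature-scaled parameter vector for the ODE core
#'
#' Applies Arrhenius scaling (V-type rates with Ea_V, half-saturation
#' constants with Ea_K, sorption rates with Ea_ads), the temperature-adjusted
#' carbon use efficiency, and the maintenance rate derived from alpha, and
#' lays everything out in the order expected by the compiled RHS.
#' @noRd
mend_parms_vector <- function(mp, fp, env) {
  fV <- arrhenius_factor(fp$Ea_V, env$T, fp$Tref)
  fK <- arrhenius_factor(fp$Ea_K, env$T, fp$Tref)
  fA <- arrhenius_factor(fp$Ea_ads, env$T, fp$Tref)
  Vmt <- derived_maintenance_rate(mp$Vg, mp$alpha)
  c(VP1 = fp$VP1 * fV, KP1 = fp$KP1 * fK,
    VP2 = fp$VP2 * fV, KP2 = fp$KP2 * fK,
    VM = fp$VM * fV, KM = fp$KM * fK,
    Kads = fp$Kads * fA, Kdes = fp$Kdes * fA, Qmax = fp$Qmax,
    fD = fp$fD, gD = fp$gD, rM = fp$rM,
    pEP1 = fp$pEP1, pEP2 = fp$pEP2, pEM = fp$pEM, rE = fp$rE,
    beta = fp$beta,
    Vg = mp$Vg * fV, Vmt = Vmt * fV, KD = mp$KD * fK,
    Yg = yg_at_temperature(mp$Yg, fp$kYg, env$T, fp$Tref),
    IP1 = env$IP1, IP2 = env$IP2, ID = env$ID)
}
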