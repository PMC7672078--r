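#' Built-in incubation collection schedules
#'
#' `ST_G` is the short-term (6-day, glucose-amended) design with headspace
#' CO2 collections at 2, 4, 8, 24, 48, 72 and 144 h and microbial biomass
#' collections at 24, 72 and 144 h.  `LT_C` is the long-term (729-day,
#' cellulose-amended) design with CO2 collections on days 1, 2, 4, 6, 11,
#' 20, 39, 64, 90, 120, 151, 229, 323, 390, 480, 571, 665 and 729 and
#' biomass collections on days 1, 4, 20, 64, 151, 323, 480 and 729.
#'
#' @param name `"ST_G"` or `"LT_C"`.
#' @return A list with components `co2_hours` and `mbc_hours`.
#' @export
incubation_schedule <- function(name = c("ST_G", "LT_C")) {
  name <- match.arg(name)
  if (name == "ST_G") {
    list(name = "ST_G",
         co2_hours = c(2, 4, 8, 24, 48, 72, 144),
         mbc_hours = c(24, 72, 144))
  } else {
    list(name = "LT_C",
         co2_hours = 24 * c(1, 2, 4, 6, 11, 20, 39, 64, 90, 120, 151, 229,
                            323, 390, 480, 571, 665, 729),
         mbc_hours = 24 * c(1, 4, 20, 64, 151, 323, 480, 729))
  }
}

.resolve_schedule <- function(schedule) {
  if (is.character(schedule)) return(incubation_schedule(schedule))
  stopifnot(is.list(schedule), all(c("co2_hours", "mbc_hours") %in% names(schedule)))
  schedule
}

#' Initial pool state for a soil
#'
#' Maps a soil initial-condition record onto the model pools: the two
#' particulate pools take the measured POC split, `M` the mineral-associated
#' carbon, `D` the dissolved carbon; the adsorbed pool starts at 1% of `M`;
#' active/dormant biomass split the measured MBC by the initial active
#' fraction `r0`; enzymes start at 1.1e-3, 1.1e-3 and 1.4e-3 mg C cm^-3.
#' A substrate pulse (1% of total soil carbon) is added to `D` for glucose
#' or to `P2` for cellulose.
#'
#' @param soil a soil record (see [generate_soil()]).
#' @param mp [microbial_params()] (supplies `r0`).
#' @param substrate `"none"`, `"glucose"` or `"cellulose"`.
#' @return A [pool_state()].
#' @export
soil_state0 <- function(soil, mp, substrate = c("none", "glucose", "cellulose")) {
  substrate <- match.arg(substrate)
  s <- pool_state(P1 = soil$poc1, P2 = soil$poc2, M = soil$moc, D = soil$doc,
                  Q = 0.01 * soil$moc,
                  BA = mp$r0 * soil$mbc, BD = (1 - mp$r0) * soil$mbc,
                  EP1 = 1.1e-3, EP2 = 1.1e-3, EM = 1.4e-3, CO2 = 0)
  pulse <- 0.01 * soil$soc
  if (substrate == "glucose") s["D"] <- s["D"] + pulse
  if (substrate == "cellulose") s["P2"] <- s["P2"] + pulse
  s
}

#' Integrate the model over a time grid
#'
#' Stiff adaptive integration (lsoda) of the pool ODE system.  The compiled
#' RHS shipped with the package is used by default; `compiled = FALSE`
#' switches to the pure-R reference RHS (identical equations, much slower).
#' Every trajectory is checked for global carbon balance:
#' change in total carbon plus cumulative CO2 must equal the integrated
#' external input to 1e-6 relative.
#'
#' @param state0 initial [pool_state()].
#' @param mp,fp,env model parameters and forcing.
#' @param times output times, hours, strictly increasing (first element is
#'   the initial time).
#' @param rtol,atol solver tolerances.
#' @param compiled use the compiled RHS (default) or the R reference.
#' @param check_balance verify the carbon-balance identity (default TRUE).
#' @return A data.frame of class `mend_trajectory`: `time` plus one column
#'   per pool, with the forcing attached as attribute `env`.
#' @export
mend_integrate <- function(state0, mp, fp, env, times,
                           rtol = 1e-8, atol = 1e-10, compiled = TRUE,
                           check_balance = TRUE) {
  if (is.unsorted(times, strictly = TRUE)) stop("times must be strictly increasing")
  y0 <- .as_state(state0)
  pv <- mend_parms_vector(mp, fp, env)
  out <- .integrate_pv(y0, pv, times, rtol = rtol, atol = atol, compiled = compiled)
  if (check_balance) {
    input_rate <- pv[["IP1"]] + pv[["IP2"]] + pv[["ID"]]
    .check_balance(out, y0, input_rate)
  }
  traj <- as.data.frame(out)
  class(traj) <- c("mend_trajectory", "data.frame")
  attr(traj, "env") <- env
  traj
}

#' @noRd
.integrate_pv <- function(y0, pv, times, rtol = 1e-8, atol = 1e-10,
                          compiled = TRUE) {
  if (compiled) {
    out <- deSolve::ode(y = y0, times = times, func = "mend_derivs",
                        parms = unname(pv), dllname = "mendfusion",
                        initfunc = "mend_init", method = "lsoda",
                        rtol = rtol, atol = atol, maxsteps = 50000)
  } else {
    out <- deSolve::ode(y = y0, times = times, func = .mend_rhs_desolve,
                        parms = pv, method = "lsoda",
                        rtol = rtol, atol = atol, maxsteps = 50000)
  }
  if (nrow(out) < length(times)) {
    stop(sprintf("ODE solver failed at t = %.6g h (reached %d of %d output times)",
                 out[nrow(out), 1], nrow(out), length(times)))
  }
  colnames(out) <- c("time", MEND_POOLS)
  out
}

#' @noRd
.check_balance <- function(out, y0, input_rate, tol = 1e-6) {
  n <- nrow(out)
  pools <- setdiff(MEND_POOLS, "CO2")
  tot0 <- sum(y0[pools]) + y0[["CO2"]]
  tot1 <- sum(out[n, pools]) + out[n, "CO2"]
  inputs <- input_rate * (out[n, "time"] - out[1, "time"])
  err <- abs(tot1 - tot0 - inputs) / max(tot0, .Machine$double.eps)
  if (is.na(err) || err > tol) {
    warning(sprintf("carbon balance violated: relative error %.3g", err))
  }
  invisible(err)
}

#' Simulate a laboratory incubation
#'
#' Closed-jar incubation at constant temperature (22 degC by default, the
#' laboratory condition) with an optional substrate pulse at t = 0 and no
#' external inputs.  The observable CO2 "rate" at each collection is the
#' mean respiration rate over the interval ending at that collection
#' (cumulative CO2 difference over elapsed time), matching headspace
#' accumulation measurements; microbial biomass is reported as the sum of
#' active and dormant pools at each biomass collection.
#'
#' @param soil soil record (see [generate_soil()]).
#' @param mp,fp model parameters.
#' @param substrate `"none"`, `"glucose"` or `"cellulose"`.
#' @param schedule a schedule name (`"ST_G"`, `"LT_C"`) or a list with
#'   `co2_hours` and `mbc_hours`.
#' @param T incubation temperature, degC.
#' @param ... passed to [mend_integrate()].
#' @return A list of class `incubation_sim` with data.frames `co2`
#'   (`time_h`, `rate`) and `mbc` (`time_h`, `value`) and the full
#'   `trajectory`.
#' @export
run_incubation <- function(soil, mp, fp, substrate = c("none", "glucose", "cellulose"),
                           schedule = "ST_G", T = 22, ...) {
  substrate <- match.arg(substrate)
  sch <- .resolve_schedule(schedule)
  co2_t <- sort(sch$co2_hours)
  mbc_t <- sort(sch$mbc_hours)
  if (any(co2_t <= 0) || any(mbc_t <= 0)) stop("collection times must be > 0")
  state0 <- soil_state0(soil, mp, substrate)
  env <- mend_env(T = T, IP1 = 0, IP2 = 0, ID = 0)
  times <- sort(unique(c(0, co2_t, mbc_t)))
  traj <- mend_integrate(state0, mp, fp, env, times, ...)
  co2cum <- traj$CO2[match(co2_t, traj$time)]
  prev_t <- c(0, co2_t[-length(co2_t)])
  prev_c <- c(0, co2cum[-length(co2cum)])
  rate <- (co2cum - prev_c) / (co2_t - prev_t)
  mbc_v <- traj$BA[match(mbc_t, traj$time)] + traj$BD[match(mbc_t, traj$time)]
  structure(list(co2 = data.frame(time_h = co2_t, rate = rate),
                 mbc = data.frame(time_h = mbc_t, value = mbc_v),
                 trajectory = traj, substrate = substrate,
                 schedule = sch$name %||% "custom", T = T),
            class = "incubation_sim")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Spin the model up to steady state
#'
#' Runs the model under constant forcing (temperature `T`, annual carbon
#' input equal to `input_frac` of the soil's initial total carbon, split
#' between the two particulate pools and the dissolved pool) until every
#' pool derivative is negligible.  Long integration chunks bring the system
#' close to equilibrium and a damped Newton iteration on the pool balance
#' then polishes the fixed point to machine precision.
#'
#' @param soil soil record; its `soc` sets the input rate.
#' @param mp,fp model parameters.
#' @param T spin-up temperature, degC (default 20, the reference).
#' @param input_frac annual input as a fraction of initial total carbon
#'   (default 0.05).
#' @param input_split fractions of the input routed to P1, P2 and D
#'   (default 0.4/0.4/0.2; litter is mostly particulate).
#' @param tol convergence tolerance on max |d pool/dt| / pool, h^-1.
#' @param max_years give up after this many simulated years.
#' @param state0 optional starting state (defaults to the soil's state).
#' @return The steady [pool_state()] (CO2 reset to 0) with attributes
#'   `env` (the forcing used) and `residual`.
#' @export
spin_up <- function(soil, mp, fp, T = 20, input_frac = 0.05,
                    input_split = c(0.4, 0.4, 0.2), tol = 1e-9,
                    max_years = 2000, state0 = NULL) {
  if (input_frac <= 0) stop("input_frac must be > 0")
  if (length(input_split) != 3 || abs(sum(input_split) - 1) > 1e-9) {
    stop("input_split must be three fractions summing to 1")
  }
  itot <- input_frac * soil$soc / 8760   # mg C cm^-3 h^-1
  env <- mend_env(T = T, IP1 = itot * input_split[1],
                  IP2 = itot * input_split[2], ID = itot * input_split[3])
  if (is.null(state0)) state0 <- soil_state0(soil, mp, "none")
  y <- .as_state(state0)
  pv <- mend_parms_vector(mp, fp, env)
  st <- .spin_to_steady(y, pv, tol = tol, max_years = max_years)
  out <- pool_state(P1 = st[["P1"]], P2 = st[["P2"]], M = st[["M"]],
                    D = st[["D"]], Q = st[["Q"]], BA = st[["BA"]],
                    BD = st[["BD"]], EP1 = st[["EP1"]], EP2 = st[["EP2"]],
                    EM = st[["EM"]], CO2 = 0)
  attr(out, "env") <- env
  attr(out, "residual") <- attr(st, "residual")
  out
}

#' @noRd
.steady_residual <- function(y, pv) {
  d <- .mend_rhs_pv(y, pv)[1:10]
  max(abs(d) / pmax(y[1:10], 1e-8))
}

#' Damped Newton iteration on the 10 pool balances (CO2 excluded)
#' @noRd
.steady_newton <- function(y, pv, tol, max_iter = 60) {
  yp <- y[1:10]
  fn <- function(x) .mend_rhs_pv(c(x, 0), pv)[1:10]
  # polish well past the declared tolerance so the fixed point is unique to
  # solver precision (the pool offset scales as residual / slowest rate)
  tol_inner <- max(tol * 1e-4, 1e-14)
  for (it in seq_len(max_iter)) {
    f0 <- fn(yp)
    res <- max(abs(f0) / pmax(yp, 1e-8))
    if (res < tol_inner) break
    J <- matrix(0, 10, 10)
    h <- pmax(abs(yp), 1e-8) * 1e-7
    for (j in 1:10) {
      xp <- yp; xp[j] <- xp[j] + h[j]
      xm <- yp; xm[j] <- pmax(xm[j] - h[j], 0)
      J[, j] <- (fn(xp) - fn(xm)) / (xp[j] - xm[j])
    }
    step <- tryCatch(solve(J, -f0), error = function(e) NULL)
    if (is.null(step)) break
    lambda <- 1
    repeat {
      cand <- yp + lambda * step
      if (all(cand >= 0) &&
          max(abs(fn(cand)) / pmax(cand, 1e-8)) < res) break
      lambda <- lambda / 2
      if (lambda < 1e-6) { cand <- yp; break }
    }
    if (identical(cand, yp)) break
    yp <- cand
  }
  out <- c(yp, 0)
  names(out) <- MEND_POOLS
  attr(out, "residual") <- max(abs(fn(yp)) / pmax(yp, 1e-8))
  out
}

#' @noRd
.spin_to_steady <- function(y, pv, tol = 1e-9, max_years = 2000) {
  years_done <- 0
  chunk <- 100
  repeat {
    res <- .steady_residual(y, pv)
    if (res < 1e-4) {   # close enough for Newton to take over
      st <- .steady_newton(y, pv, tol = tol)
      if (attr(st, "residual") < tol) return(st)
    }
    if (years_done >= max_years) {
      stop(sprintf("no steady state within %d years (residual %.3g h^-1)",
                   max_years, res))
    }
    hours <- min(chunk, max_years - years_done) * 8760
    out <- .integrate_pv(y, pv, c(0, hours), rtol = 1e-8, atol = 1e-10)
    y <- out[2, MEND_POOLS]
    y[["CO2"]] <- 0
    years_done <- years_done + hours / 8760
    chunk <- min(chunk * 2, 500)
  }
}

#' Five-decade warming projection from a steady baseline
#'
#' Starting from a spin-up steady state, runs the model for `years` years
#' under the same constant inputs at the baseline temperature and at the
#' warmed temperature, and reports the relative SOC change (%) of the
#' warmed run against the baseline run at the end of the simulation, plus
#' the transient relative-change time series.
#'
#' @param steady a [spin_up()] result (its `env` attribute supplies the
#'   baseline forcing).
#' @param mp,fp model parameters.
#' @param dT warming, degC (default +5).
#' @param years projection horizon (default 50).
#' @param step_years output resolution of the transient series.
#' @return A list of class `warming_projection` with `baseline_soc`,
#'   `warmed_soc`, `rel_change_pct` and a `series` data.frame.
#' @export
project_warming <- function(steady, mp, fp, dT = 5, years = 50,
                            step_years = 0.5) {
  env <- attr(steady, "env")
  if (is.null(env)) stop("steady must carry its spin-up forcing (attr 'env')")
  y0 <- .as_state(steady)
  y0[["CO2"]] <- 0
  times <- seq(0, years * 8760, by = step_years * 8760)
  pools <- setdiff(MEND_POOLS, "CO2")
  env_w <- mend_env(T = env$T + dT, IP1 = env$IP1, IP2 = env$IP2, ID = env$ID)
  base <- .integrate_pv(y0, mend_parms_vector(mp, fp, env), times)
  warm <- .integrate_pv(y0, mend_parms_vector(mp, fp, env_w), times)
  soc_b <- rowSums(base[, pools, drop = FALSE])
  soc_w <- rowSums(warm[, pools, drop = FALSE])
  rel <- (soc_w - soc_b) / soc_b * 100
  n <- length(times)
  structure(list(baseline_soc = soc_b[n], warmed_soc = soc_w[n],
                 rel_change_pct = rel[n],
                 series = data.frame(time_yr = times / 8760,
                                     rel_change_pct = rel),
                 dT = dT, years = years),
            class = "warming_projection")
}

#' @export
print.warming_projection <- function(x, ...) {
  cat(sprintf("Warming projection (+%g degC, %g y): SOC %.4g -> %.4g mg C cm-3 (%+.2f%%)\n",
              x$dT, x$years, x$baseline_soc, x$warmed_soc, x$rel_change_pct))
  invisible(x)
}

#' Steady-state SOC response to warming across carbon use efficiencies
#'
#' For each value of the intrinsic carbon use efficiency, computes the
#' steady-state total SOC at the reference temperature and at the warmed
#' temperature (same constant inputs) and reports the relative change (%).
#' The sign of this response switches at a threshold Yg: below it the
#' CUE-decline feedback dominates and warming gains carbon, above it the
#' kinetic acceleration dominates and warming loses carbon.
#'
#' @param yg_grid carbon use efficiency values to evaluate.
#' @param mp,fp model parameters (`mp$Yg` is replaced by each grid value).
#' @param soil soil record used for initial state and input rate (default
#'   a representative generated soil).
#' @param dT warming, degC.
#' @param ... passed to [spin_up()].
#' @return data.frame of class `yg_response` (`Yg`, `soc_base`, `soc_warm`,
#'   `rel_change_pct`).
#' @export
yg_response_curve <- function(yg_grid = seq(0.2, 0.6, by = 0.02),
                              mp = microbial_defaults(), fp = fixed_params(),
                              soil = NULL, dT = 5, ...) {
  if (is.null(soil)) soil <- generate_soil(seed = 1)
  res <- lapply(yg_grid, function(yg) {
    mpi <- microbial_params(mp$r0, mp$Vg, mp$alpha, mp$KD, yg)
    base <- spin_up(soil, mpi, fp, T = fp$Tref, ...)
    env <- attr(base, "env")
    warm <- spin_up(soil, mpi, fp, T = fp$Tref + dT, state0 = base, ...)
    c(soc_base = soc(base), soc_warm = soc(warm))
  })
  res <- do.call(rbind, res)
  out <- data.frame(Yg = yg_grid, soc_base = res[, 1], soc_warm = res[, 2])
  out$rel_change_pct <- (out$soc_warm - out$soc_base) / out$soc_base * 100
  class(out) <- c("yg_response", "data.frame")
  out
}

#' Zero crossings of a Yg response curve
#'
#' Locates the carbon use efficiency at which the warming response of
#' steady-state SOC changes sign, by linear interpolation between grid
#' points of opposite sign.
#'
#' @param curve a [yg_response_curve()] result.
#' @return Numeric vector of crossing locations (length 0 if none).
#' @export
yg_sign_change <- function(curve) {
  y <- curve$rel_change_pct
  x <- curve$Yg
  i <- which(y[-length(y)] * y[-1] < 0)
  ex <- which(y == 0)
  cross <- x[i] + (0 - y[i]) * (x[i + 1] - x[i]) / (y[i + 1] - y[i])
  sort(c(cross, x[ex]))
}
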