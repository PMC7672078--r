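#' Critical objective function threshold (COFI)
#'
#' The feasible parameter region around a calibration optimum is bounded by
#' `Jcr = Jopt * (1 + p / (n - p) * F(alpha, p, n - p))`, where `F` is the
#' upper-tail F quantile, `n` the number of fitted observations and `p` the
#' number of calibrated parameters.
#'
#' @param Jopt minimum objective function value (>= 0).
#' @param n number of observations (`n > p`).
#' @param p number of calibrated parameters.
#' @param alpha significance level (default 0.05).
#' @return `Jcr >= Jopt`.
#' @export
#' @examples
#' cofi_threshold(0.2, n = 25, p = 5)
cofi_threshold <- function(Jopt, n, p, alpha = 0.05) {
  if (Jopt < 0) stop("Jopt must be >= 0")
  if (n <= p || p <= 0) stop("need n > p > 0")
  Jopt * (1 + p / (n - p) * stats::qf(1 - alpha, p, n - p))
}

#' Feasible parameter ensemble
#'
#' Filters a calibration archive down to the vectors whose objective value
#' does not exceed the COFI threshold; these constitute the feasible
#' parameter space used for uncertainty quantification.
#'
#' @param archive data.frame with one row per evaluated parameter vector
#'   and a `J` column (as produced by [sce_optimize()]).
#' @param Jcr threshold from [cofi_threshold()].
#' @return The feasible subset (class `parameter_ensemble`), with `Jcr`
#'   attached as an attribute.  An empty result triggers a warning, not an
#'   error.
#' @export
feasible_ensemble <- function(archive, Jcr) {
  if (!is.data.frame(archive) || !"J" %in% names(archive) || nrow(archive) == 0) {
    stop("archive must be a non-empty data.frame with a J column")
  }
  ens <- archive[archive$J <= Jcr, , drop = FALSE]
  if (nrow(ens) == 0) warning("feasible ensemble is empty (Jcr below all archived J)")
  rownames(ens) <- NULL
  attr(ens, "Jcr") <- Jcr
  class(ens) <- c("parameter_ensemble", "data.frame")
  ens
}

#' Per-parameter uncertainty intervals of a feasible ensemble
#'
#' @param ensemble a [feasible_ensemble()] result.
#' @return data.frame with `parameter`, `lo`, `hi`, `width`.
#' @export
cofi_intervals <- function(ensemble) {
  pars <- setdiff(names(ensemble), "J")
  if (nrow(ensemble) == 0) {
    return(data.frame(parameter = pars, lo = NA_real_, hi = NA_real_,
                      width = NA_real_))
  }
  data.frame(parameter = pars,
             lo = vapply(pars, function(p) min(ensemble[[p]]), 0),
             hi = vapply(pars, function(p) max(ensemble[[p]]), 0),
             width = vapply(pars, function(p) diff(range(ensemble[[p]])), 0),
             row.names = NULL)
}

#' Kruskal-Wallis comparison of two parameter ensembles
#'
#' Non-parametric rank test of whether the feasible distributions of each
#' parameter differ between two calibrations (e.g. short- versus long-term
#' incubation datasets); significance is judged at p < 0.05.  When a
#' parameter is identical across both ensembles the test is undefined and
#' p = 1 is reported.
#'
#' @param ensA,ensB data.frames of parameter vectors (>= 2 rows each);
#'   a `J` column, if present, is ignored.
#' @return data.frame with `parameter`, `statistic` (tie-corrected H),
#'   `p_value`, `significant`.
#' @export
kruskal_wallis_compare <- function(ensA, ensB) {
  pars <- setdiff(intersect(names(ensA), names(ensB)), "J")
  if (nrow(ensA) < 2 || nrow(ensB) < 2) stop("each ensemble needs >= 2 members")
  rows <- lapply(pars, function(p) {
    a <- ensA[[p]]; b <- ensB[[p]]
    if (length(unique(c(a, b))) == 1) {
      return(data.frame(parameter = p, statistic = 0, p_value = 1))
    }
    kt <- stats::kruskal.test(list(a, b))
    data.frame(parameter = p, statistic = unname(kt$statistic),
               p_value = kt$p.value)
  })
  out <- do.call(rbind, rows)
  out$significant <- out$p_value < 0.05
  out
}

#' Paired t comparison of best-fit parameter estimates
#'
#' Classic paired t-test on the case-wise differences between short- and
#' long-term best-fit estimates of one parameter, with direction counts
#' (how many pairs have short > long).  Zero variance of the differences is
#' reported via a `degenerate` flag rather than an error.
#'
#' @param short_best,long_best equal-length numeric vectors (paired by
#'   case), `n >= 2`.
#' @return List with `t`, `p_value`, `mean_difference`, `n_short_higher`,
#'   `n`, `degenerate`.
#' @export
paired_t_compare <- function(short_best, long_best) {
  if (length(short_best) != length(long_best)) stop("samples must be paired")
  n <- length(short_best)
  if (n < 2) stop("need at least two pairs")
  d <- short_best - long_best
  if (stats::sd(d) == 0) {
    return(list(t = if (mean(d) == 0) 0 else sign(mean(d)) * Inf,
                p_value = if (mean(d) == 0) 1 else 0,
                mean_difference = mean(d),
                n_short_higher = sum(d > 0), n = n, degenerate = TRUE))
  }
  tt <- stats::t.test(short_best, long_best, paired = TRUE)
  list(t = unname(tt$statistic), p_value = tt$p.value,
       mean_difference = unname(tt$estimate),
       n_short_higher = sum(d > 0), n = n, degenerate = FALSE)
}

#' Parametric sensitivity index
#'
#' `SI = |log10|Yhigh| - log10|Ylow|| / |log10|Xhigh| - log10|Xlow||`:
#' the order-of-magnitude response of a model output to sweeping one
#' parameter across its prior range.  Symmetric in the high/low labels of
#' both axes.
#'
#' @param Yhigh,Ylow model output at the high/low parameter value.
#' @param Xhigh,Xlow the high/low parameter values (`Xhigh != Xlow`).
#' @return Non-negative scalar.
#' @export
#' @examples
#' sensitivity_index(100, 1, 10, 0.1)
sensitivity_index <- function(Yhigh, Ylow, Xhigh, Xlow) {
  if (any(c(Yhigh, Ylow, Xhigh, Xlow) == 0)) stop("arguments must be nonzero")
  if (Xhigh == Xlow) stop("Xhigh and Xlow must differ")
  abs(log10(abs(Yhigh)) - log10(abs(Ylow))) /
    abs(log10(abs(Xhigh)) - log10(abs(Xlow)))
}

#' Steady-state sensitivity sweep over the microbial parameters
#'
#' For each calibrated parameter, runs the model to steady state with the
#' parameter at the low and at the high end of its prior range (all other
#' parameters at their reference values) and computes the sensitivity
#' index of each steady pool, total SOC, total MBC and the CO2 efflux.
#'
#' The sweep uses the calibration prior ranges, with one adjustment: below
#' a growth rate of about 0.002 h^-1 growth cannot offset mortality and
#' enzyme production at any substrate saturation, the biomass collapses and
#' the input-forced system has no steady state, so the low sweep limit for
#' `Vg` is raised to the smallest viable rate.
#'
#' @param mp reference [microbial_params()].
#' @param fp [fixed_params()].
#' @param soil soil record (default a representative generated soil).
#' @param bounds sweep ranges (default: [microbial_bounds()] with the `Vg`
#'   low limit raised to 0.002 h^-1, see above).
#' @param ... passed to [spin_up()].
#' @return data.frame: one row per parameter, one column per output.
#' @export
sensitivity_sweep <- function(mp = microbial_defaults(), fp = fixed_params(),
                              soil = NULL, bounds = NULL, ...) {
  if (is.null(soil)) soil <- generate_soil(seed = 1)
  if (is.null(bounds)) {
    bounds <- microbial_bounds()
    bounds["lo", "Vg"] <- max(bounds["lo", "Vg"], 0.002)
  }
  outputs_at <- function(mpi) {
    st <- spin_up(soil, mpi, fp, ...)
    env <- attr(st, "env")
    eff <- mend_rhs(st, mpi, fp, env)[["CO2"]]
    c(st[setdiff(MEND_POOLS, "CO2")], SOC = soc(st), MBC = mbc(st),
      CO2_efflux = eff)
  }
  pars <- colnames(bounds)
  rows <- lapply(pars, function(p) {
    mp_lo <- mp; mp_lo[[p]] <- bounds["lo", p]
    mp_hi <- mp; mp_hi[[p]] <- bounds["hi", p]
    y_lo <- outputs_at(do.call(microbial_params, mp_lo[c("r0", "Vg", "alpha", "KD", "Yg")]))
    y_hi <- outputs_at(do.call(microbial_params, mp_hi[c("r0", "Vg", "alpha", "KD", "Yg")]))
    si <- mapply(function(h, l) {
      if (h == 0 || l == 0) return(NA_real_)
      sensitivity_index(h, l, bounds["hi", p], bounds["lo", p])
    }, y_hi, y_lo)
    as.data.frame(as.list(si))
  })
  out <- do.call(rbind, rows)
  out <- cbind(parameter = pars, out)
  rownames(out) <- NULL
  out
}
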