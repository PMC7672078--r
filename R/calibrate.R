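#' Mean absolute relative error
#'
#' `MARE = mean(|sim - obs| / |obs|)`; the calibration metric used for
#' short observation series.
#'
#' @param obs,sim numeric vectors of equal length; `obs` must be nonzero.
#' @return Non-negative scalar.
#' @export
#' @examples
#' mare(c(1, 2, 4), c(2, 1, 2))
mare <- function(obs, sim) {
  if (length(obs) != length(sim)) stop("obs and sim must have equal length")
  if (any(obs == 0)) stop("MARE undefined for zero observations")
  mean(abs(sim - obs) / abs(obs))
}

#' Coefficient of determination
#'
#' `R^2 = 1 - sum((sim - obs)^2) / sum((obs - mean(obs))^2)`; at most 1,
#' can be negative for fits worse than the observation mean.
#'
#' @param obs,sim numeric vectors of equal length, `n >= 2`, `obs` not
#'   constant.
#' @return Scalar `<= 1`.
#' @export
#' @examples
#' r_squared(c(1, 2, 3), c(1.1, 1.9, 3.2))
r_squared <- function(obs, sim) {
  if (length(obs) != length(sim)) stop("obs and sim must have equal length")
  if (length(obs) < 2) stop("R^2 requires at least two observations")
  ss_tot <- sum((obs - mean(obs))^2)
  if (ss_tot == 0) stop("R^2 undefined for constant observations")
  1 - sum((sim - obs)^2) / ss_tot
}

#' Replicate-averaged observation series of a dataset
#'
#' Calibration is performed against case-level series: replicates are
#' averaged per collection time before entering the objective.
#'
#' @param data an incubation dataset (see [generate_incubation_dataset()]).
#' @return List with data.frames `co2` (`time_h`, `rate`) and `mbc`
#'   (`time_h`, `value`).
#' @export
case_series <- function(data) {
  co2 <- stats::aggregate(rate ~ time_h, data = data$co2, FUN = mean)
  mbc <- stats::aggregate(value ~ time_h, data = data$mbc, FUN = mean)
  list(co2 = co2[order(co2$time_h), ], mbc = mbc[order(mbc$time_h), ])
}

#' Weighted calibration objective for one incubation dataset
#'
#' Simulates the incubation with the candidate microbial parameters and
#' scores the fit as `J = w1 * J1 + (1 - w1) * J2`, where `J1` scores the
#' CO2 series and `J2` the microbial biomass series.  MARE is used for a
#' series with 10 or fewer observations (R^2 is unreliable for small n);
#' longer CO2 series are scored as `1 - R^2`.  Biomass series are always
#' short here, so `J2` is MARE.  A failed simulation scores `+Inf` so a
#' global optimizer can continue past pathological parameter draws.
#'
#' @param mp candidate [microbial_params()].
#' @param data incubation dataset.
#' @param fp [fixed_params()].
#' @param w1 weight of the CO2 component, in `[0, 1]` (default 0.5).
#' @param detail return components as attributes (default TRUE).
#' @return `J`, with attributes `J1`, `J2` and `co2_metric` when
#'   `detail = TRUE`.
#' @export
incubation_objective <- function(mp, data, fp, w1 = 0.5, detail = TRUE) {
  if (w1 < 0 || w1 > 1) stop("w1 must be in [0, 1]")
  obs <- case_series(data)
  if (nrow(obs$co2) < 1 || nrow(obs$mbc) < 1) {
    stop("dataset needs at least one CO2 and one MBC observation")
  }
  sim <- tryCatch(
    run_incubation(data$soil, mp, fp, substrate = data$case$substrate,
                   schedule = list(co2_hours = obs$co2$time_h,
                                   mbc_hours = obs$mbc$time_h),
                   rtol = 1e-7, atol = 1e-9, check_balance = FALSE),
    error = function(e) NULL)
  if (is.null(sim)) {
    J <- Inf
    if (detail) attributes(J) <- list(J1 = Inf, J2 = Inf, co2_metric = NA_character_)
    return(J)
  }
  co2_metric <- if (nrow(obs$co2) <= 10) "mare" else "one_minus_r2"
  J1 <- if (co2_metric == "mare") mare(obs$co2$rate, sim$co2$rate)
        else 1 - r_squared(obs$co2$rate, sim$co2$rate)
  J2 <- mare(obs$mbc$value, sim$mbc$value)
  J <- w1 * J1 + (1 - w1) * J2
  if (detail) attributes(J) <- list(J1 = J1, J2 = J2, co2_metric = co2_metric)
  J
}

#' Shuffled Complex Evolution (SCE-UA) global optimizer
#'
#' Minimizes `fn` over a box.  The population of `ngs * (2k + 1)` points is
#' drawn by Latin hypercube sampling, ranked and dealt into `ngs` complexes;
#' each complex evolves by competitive simplex steps (reflection of the
#' subcomplex worst through the centroid, contraction on failure, random
#' replacement within the bounds when both fail), after which the complexes
#' are shuffled.  Iteration stops when the best objective value has improved
#' by less than `rel_tol` (relative) over the last `tol_loops` shuffling
#' loops, or when the evaluation budget is exhausted.  Every evaluation is
#' archived for downstream feasible-region (COFI) analysis.
#'
#' @param fn scalar objective, called with a named numeric parameter vector.
#' @param bounds 2 x k matrix (rows `lo`, `hi`; named columns).
#' @param ngs number of complexes (>= 2).
#' @param max_evals evaluation budget.
#' @param rel_tol,tol_loops convergence rule (see above).
#' @param seed optional RNG seed; fixing it makes the run fully
#'   reproducible.
#' @return List of class `sce_result`: `par`, `value` (Jopt), `archive`
#'   (data.frame of every evaluated vector and its J), `n_evals`,
#'   `n_loops`, `converged`.
#' @export
#' @examples
#' sphere <- function(x) sum(x^2)
#' b <- rbind(lo = rep(-5, 5), hi = rep(5, 5))
#' colnames(b) <- paste0("x", 1:5)
#' r <- sce_optimize(sphere, b, seed = 1)
#' r$value
sce_optimize <- function(fn, bounds, ngs = 4, max_evals = 5000,
                         rel_tol = 1e-4, tol_loops = 10, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(is.matrix(bounds), nrow(bounds) == 2)
  if (ngs < 2) stop("at least two complexes are required")
  lo <- bounds[1, ]; hi <- bounds[2, ]
  if (any(!is.finite(lo)) || any(!is.finite(hi)) || any(hi <= lo)) {
    stop("bounds must be finite with hi > lo")
  }
  k <- ncol(bounds)
  pnames <- colnames(bounds)
  if (is.null(pnames)) pnames <- paste0("p", seq_len(k))
  npg <- 2 * k + 1           # points per complex
  nps <- k + 1               # subcomplex (simplex) size
  nspl <- npg                # evolution steps per complex per shuffle
  s <- ngs * npg

  arch_x <- matrix(NA_real_, nrow = max_evals + s, ncol = k)
  arch_j <- rep(NA_real_, max_evals + s)
  n_eval <- 0
  evalfn <- function(x) {
    n_eval <<- n_eval + 1
    j <- as.numeric(fn(stats::setNames(x, pnames)))[1]
    if (is.na(j)) j <- Inf
    arch_x[n_eval, ] <<- x
    arch_j[n_eval] <<- j
    j
  }

  X <- lhs::randomLHS(s, k)
  X <- sweep(sweep(X, 2, hi - lo, `*`), 2, lo, `+`)
  J <- apply(X, 1, evalfn)

  sub_prob <- 2 * (npg + 1 - seq_len(npg)) / (npg * (npg + 1))
  best_hist <- numeric(0)
  converged <- FALSE
  n_loops <- 0

  repeat {
    ord <- order(J)
    X <- X[ord, , drop = FALSE]; J <- J[ord]
    best_hist <- c(best_hist, J[1])
    n_loops <- length(best_hist)
    if (n_loops > tol_loops) {
      prev <- best_hist[n_loops - tol_loops]
      impr <- (prev - J[1]) / max(abs(prev), .Machine$double.eps)
      if (impr < rel_tol) { converged <- TRUE; break }
    }
    if (n_eval >= max_evals) break

    for (g in seq_len(ngs)) {
      ci <- seq(g, s, by = ngs)      # deal ranked points into complex g
      cx <- X[ci, , drop = FALSE]; cj <- J[ci]
      for (step in seq_len(nspl)) {
        if (n_eval >= max_evals) break
        sub <- sort(sample.int(npg, nps, prob = sub_prob))
        sx <- cx[sub, , drop = FALSE]; sj <- cj[sub]
        w <- which.max(sj)
        centroid <- colMeans(sx[-w, , drop = FALSE])
        cand <- 2 * centroid - sx[w, ]
        if (any(cand < lo) || any(cand > hi)) {
          cand <- lo + stats::runif(k) * (hi - lo)
        }
        jc <- evalfn(cand)
        if (jc >= sj[w]) {
          cand <- (centroid + sx[w, ]) / 2
          jc <- evalfn(cand)
          if (jc >= sj[w]) {
            cand <- lo + stats::runif(k) * (hi - lo)
            jc <- evalfn(cand)
          }
        }
        if (jc < sj[w]) {
          cx[sub[w], ] <- cand; cj[sub[w]] <- jc
        }
        ord2 <- order(cj)
        cx <- cx[ord2, , drop = FALSE]; cj <- cj[ord2]
      }
      X[ci, ] <- cx; J[ci] <- cj
    }
    if (n_eval >= max_evals) {
      ord <- order(J); X <- X[ord, , drop = FALSE]; J <- J[ord]
      best_hist <- c(best_hist, J[1])
      break
    }
  }

  if (!converged) {
    warning(sprintf("SCE stopped at the evaluation budget (%d) before convergence",
                    max_evals))
  }
  archive <- as.data.frame(arch_x[seq_len(n_eval), , drop = FALSE])
  names(archive) <- pnames
  archive$J <- arch_j[seq_len(n_eval)]
  ibest <- which.min(archive$J)
  structure(list(par = stats::setNames(as.numeric(archive[ibest, pnames]), pnames),
                 value = archive$J[ibest], archive = archive,
                 n_evals = n_eval, n_loops = length(best_hist),
                 converged = converged, seed = seed),
            class = "sce_result")
}

#' @export
print.sce_result <- function(x, ...) {
  cat(sprintf("SCE-UA: Jopt = %.6g after %d evaluations (%d loops, %s)\n",
              x$value, x$n_evals, x$n_loops,
              if (x$converged) "converged" else "budget reached"))
  print(x$par)
  invisible(x)
}

#' Calibrate the five microbial parameters against one incubation dataset
#'
#' Wraps [incubation_objective()] and [sce_optimize()]: searches the prior
#' box for the parameter vector minimizing the weighted CO2/biomass misfit,
#' and returns the best fit together with the full evaluation archive
#' needed for COFI uncertainty analysis.
#'
#' @param data incubation dataset.
#' @param fp [fixed_params()].
#' @param w1 CO2 weight of the objective.
#' @param bounds prior bounds (default [microbial_bounds()]).
#' @param ngs,max_evals,seed passed to [sce_optimize()].
#' @return List of class `calibration_result`: `par` (a
#'   [microbial_params()]), `Jopt`, `J1`, `J2`, `co2_metric`, `n_obs`,
#'   `archive`, `converged`, `seed`.
#' @export
calibrate_case <- function(data, fp, w1 = 0.5, bounds = microbial_bounds(),
                           ngs = 4, max_evals = 5000, seed = NULL) {
  fn <- function(theta) {
    incubation_objective(.mp_from_vector(theta), data, fp, w1 = w1,
                         detail = FALSE)
  }
  fit <- sce_optimize(fn, bounds, ngs = ngs, max_evals = max_evals, seed = seed)
  best_mp <- .mp_from_vector(fit$par)
  J <- incubation_objective(best_mp, data, fp, w1 = w1, detail = TRUE)
  obs <- case_series(data)
  structure(list(par = best_mp, Jopt = fit$value,
                 J1 = attr(J, "J1"), J2 = attr(J, "J2"),
                 co2_metric = attr(J, "co2_metric"),
                 w1 = w1,
                 n_obs = nrow(obs$co2) + nrow(obs$mbc),
                 n_co2 = nrow(obs$co2), n_mbc = nrow(obs$mbc),
                 archive = fit$archive, n_evals = fit$n_evals,
                 converged = fit$converged, seed = seed),
            class = "calibration_result")
}

#' @export
print.calibration_result <- function(x, ...) {
  cat(sprintf("Calibration: Jopt = %.5g (J1 = %.5g [%s], J2 = %.5g [mare]), %d evals\n",
              x$Jopt, x$J1, x$co2_metric, x$J2, x$n_evals))
  print(x$par)
  invisible(x)
}

#' Goodness-of-fit gates for a calibration
#'
#' A calibration is satisfactory when MARE-scored components are at most
#' 0.5 and R^2-scored components reach at least 0.6 (both bounds
#' inclusive).
#'
#' @param result a [calibrate_case()] result.
#' @return data.frame with one row per objective component: `component`,
#'   `metric`, `value`, `threshold`, `pass`.
#' @export
check_fit_criteria <- function(result) {
  rows <- list()
  if (identical(result$co2_metric, "mare")) {
    rows$co2 <- data.frame(component = "CO2", metric = "MARE",
                           value = result$J1, threshold = 0.5,
                           pass = result$J1 <= 0.5)
  } else {
    r2 <- 1 - result$J1
    rows$co2 <- data.frame(component = "CO2", metric = "R2",
                           value = r2, threshold = 0.6,
                           pass = r2 >= 0.6)
  }
  rows$mbc <- data.frame(component = "MBC", metric = "MARE",
                         value = result$J2, threshold = 0.5,
                         pass = result$J2 <= 0.5)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
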