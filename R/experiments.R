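#' Parameter-recovery experiment on synthetic long-term incubations
#'
#' Generates `n_trials` independent synthetic long-term cellulose datasets
#' (random soils, random true parameters drawn inside the prior box and
#' bracketing the reported best-fit ranges, multiplicative measurement
#' noise), calibrates each with SCE-UA, and scores recovery: the absolute
#' error of each recovered parameter and whether the truth falls inside the
#' COFI feasible interval of each parameter.
#'
#' @param n_trials number of synthetic datasets (default 20).
#' @param seed base RNG seed; trial `i` derives its generator and optimizer
#'   seeds from it.
#' @param noise_cv measurement noise, `c(co2 = , mbc = )`.
#' @param max_evals SCE evaluation budget per calibration.
#' @param fp [fixed_params()].
#' @param schedule collection schedule (default `"LT_C"`).
#' @return data.frame with one row per trial: true and recovered parameter
#'   values, absolute errors, `n_cover` (parameters whose COFI interval
#'   contains the truth), `Jopt` and `J_truth`.
#' @export
recovery_experiment <- function(n_trials = 20, seed = 1,
                                noise_cv = c(co2 = 0.05, mbc = 0.10),
                                max_evals = 5000, fp = fixed_params(),
                                schedule = "LT_C") {
  rows <- lapply(seq_len(n_trials), function(i) {
    set.seed(seed * 1000 + i)
    soil <- generate_soil(site = sprintf("S%02d", i))
    truth <- .draw_true_params()
    d <- generate_incubation_dataset(soil, truth, schedule = schedule,
                                     noise_cv = noise_cv, fp = fp,
                                     seed = seed * 1000 + 500 + i)
    fit <- suppressWarnings(
      calibrate_case(d, fp, max_evals = max_evals, seed = seed * 1000 + 750 + i))
    jcr <- cofi_threshold(fit$Jopt, n = fit$n_obs, p = 5)
    iv <- cofi_intervals(suppressWarnings(feasible_ensemble(fit$archive, jcr)))
    tv <- unlist(unclass(truth))
    fv <- unlist(unclass(fit$par))
    cover <- vapply(names(tv), function(p) {
      tv[[p]] >= iv$lo[iv$parameter == p] & tv[[p]] <= iv$hi[iv$parameter == p]
    }, TRUE)
    out <- data.frame(trial = i, t(tv), t(stats::setNames(fv, paste0(names(fv), "_hat"))),
                      t(stats::setNames(abs(fv - tv), paste0(names(fv), "_err"))),
                      n_cover = sum(cover), Jopt = fit$Jopt,
                      J_truth = as.numeric(incubation_objective(truth, d, fp,
                                                                detail = FALSE)))
    out
  })
  do.call(rbind, rows)
}

#' Duration-information contrast on one synthetic truth
#'
#' Calibrates truncations of the same synthetic long-term cellulose dataset
#' (e.g. the 6-day and the full 729-day versions) and reports, per
#' duration, the best fit and the COFI feasible-interval width of each
#' parameter.  Shorter truncations carry less information, which shows up
#' as wider feasible intervals, particularly for the DOC half-saturation
#' constant and the carbon use efficiency.
#'
#' @param durations truncation horizons in days (default `c(6, 729)`).
#' @param seed base RNG seed.
#' @param noise_cv measurement noise.
#' @param max_evals SCE evaluation budget per calibration.
#' @param fp [fixed_params()].
#' @return List with `truth` (the generating parameters) and `widths`
#'   (data.frame: duration, parameter, lo, hi, width, Jopt, n_obs).
#' @export
duration_contrast <- function(durations = c(6, 729), seed = 1,
                              noise_cv = c(co2 = 0.05, mbc = 0.10),
                              max_evals = 5000, fp = fixed_params()) {
  set.seed(seed * 1000 + 77)
  soil <- generate_soil()
  truth <- .draw_true_params()
  full <- generate_incubation_dataset(soil, truth, schedule = "LT_C",
                                      noise_cv = noise_cv, fp = fp,
                                      seed = seed * 1000 + 78)
  rows <- lapply(durations, function(dd) {
    td <- truncate_dataset(full, dd)
    fit <- suppressWarnings(
      calibrate_case(td, fp, max_evals = max_evals,
                     seed = seed * 1000 + 80 + round(dd)))
    jcr <- cofi_threshold(fit$Jopt, n = fit$n_obs, p = 5)
    iv <- cofi_intervals(suppressWarnings(feasible_ensemble(fit$archive, jcr)))
    cbind(duration_d = dd, iv, Jopt = fit$Jopt, n_obs = fit$n_obs)
  })
  list(truth = truth, widths = do.call(rbind, rows))
}

#' Short- versus long-schedule calibration contrast
#'
#' The comparison machinery of the incubation-duration analysis: generates
#' short-schedule (glucose, 6-day) and long-schedule (cellulose, 729-day)
#' datasets from the same soil and true parameters, calibrates both, and
#' reports the per-parameter direction of the difference plus the
#' Kruskal-Wallis comparison of the two feasible ensembles.  The direction
#' itself is data-dependent; this harness reproduces the procedure, not a
#' fixed outcome.
#'
#' @param seed base RNG seed.
#' @param noise_cv measurement noise.
#' @param max_evals SCE evaluation budget per calibration.
#' @param fp [fixed_params()].
#' @return List with `truth`, `best` (data.frame of short/long best fits
#'   and their difference) and `kw` (per-parameter ensemble comparison).
#' @export
schedule_contrast <- function(seed = 1, noise_cv = c(co2 = 0.05, mbc = 0.10),
                              max_evals = 5000, fp = fixed_params()) {
  set.seed(seed * 1000 + 17)
  soil <- generate_soil()
  truth <- .draw_true_params()
  ds <- generate_incubation_dataset(soil, truth, schedule = "ST_G",
                                    substrate = "glucose", noise_cv = noise_cv,
                                    fp = fp, seed = seed * 1000 + 18)
  dl <- generate_incubation_dataset(soil, truth, schedule = "LT_C",
                                    substrate = "cellulose", noise_cv = noise_cv,
                                    fp = fp, seed = seed * 1000 + 19)
  fs <- suppressWarnings(calibrate_case(ds, fp, max_evals = max_evals,
                                        seed = seed * 1000 + 20))
  fl <- suppressWarnings(calibrate_case(dl, fp, max_evals = max_evals,
                                        seed = seed * 1000 + 21))
  es <- suppressWarnings(feasible_ensemble(
    fs$archive, cofi_threshold(fs$Jopt, fs$n_obs, 5)))
  el <- suppressWarnings(feasible_ensemble(
    fl$archive, cofi_threshold(fl$Jopt, fl$n_obs, 5)))
  sv <- unlist(unclass(fs$par)); lv <- unlist(unclass(fl$par))
  list(truth = truth,
       best = data.frame(parameter = names(sv), short = sv, long = lv,
                         short_minus_long = sv - lv, row.names = NULL),
       kw = if (nrow(es) >= 2 && nrow(el) >= 2)
         kruskal_wallis_compare(es, el))
}
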