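#' Write incubation datasets to a tidy CSV
#'
#' One measurement per row: case labels (`site`, `ecosystem`, `substrate`,
#' `schedule`), `variable` (`"CO2"` or `"MBC"`), `time_h`, `value`,
#' `replicate`.  Numeric values are written with 17 significant digits so
#' a write/read round trip is lossless.
#'
#' @param datasets a single incubation dataset or a list of them.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_incubation_csv <- function(datasets, path) {
  if (inherits(datasets, "incubation_data")) datasets <- list(datasets)
  rows <- lapply(datasets, function(d) {
    rbind(
      data.frame(site = d$case$site, ecosystem = d$case$ecosystem,
                 substrate = d$case$substrate, schedule = d$case$schedule,
                 variable = "CO2", time_h = d$co2$time_h,
                 value = d$co2$rate, replicate = d$co2$replicate),
      data.frame(site = d$case$site, ecosystem = d$case$ecosystem,
                 substrate = d$case$substrate, schedule = d$case$schedule,
                 variable = "MBC", time_h = d$mbc$time_h,
                 value = d$mbc$value, replicate = d$mbc$replicate))
  })
  df <- do.call(rbind, rows)
  df$time_h <- sprintf("%.17g", df$time_h)
  df$value <- sprintf("%.17g", df$value)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Write soil records to CSV
#' @param soils a `soil_init` or list of them.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_soil_csv <- function(soils, path) {
  if (inherits(soils, "soil_init")) soils <- list(soils)
  df <- do.call(rbind, lapply(soils, function(s) {
    data.frame(site = s$site, ecosystem = s$ecosystem,
               poc1 = s$poc1, poc2 = s$poc2, moc = s$moc, doc = s$doc,
               mbc = s$mbc, soc = s$soc, bulk_density = s$bulk_density)
  }))
  for (nm in c("poc1", "poc2", "moc", "doc", "mbc", "soc", "bulk_density")) {
    df[[nm]] <- sprintf("%.17g", df[[nm]])
  }
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read soil records from CSV
#' @param path CSV written by [write_soil_csv()] (or equivalent layout).
#' @return Named list of `soil_init` records, keyed `site/ecosystem`.
#' @export
read_soil_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  req <- c("site", "ecosystem", "poc1", "poc2", "moc", "doc", "mbc", "soc")
  miss <- setdiff(req, names(df))
  if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "))
  out <- lapply(seq_len(nrow(df)), function(i) {
    structure(list(site = df$site[i], ecosystem = df$ecosystem[i],
                   poc1 = df$poc1[i], poc2 = df$poc2[i], moc = df$moc[i],
                   doc = df$doc[i], mbc = df$mbc[i], soc = df$soc[i],
                   bulk_density = if ("bulk_density" %in% names(df))
                     df$bulk_density[i] else NA_real_),
              class = "soil_init")
  })
  names(out) <- paste(df$site, df$ecosystem, sep = "/")
  out
}

#' Read incubation datasets from a tidy CSV
#'
#' Inverse of [write_incubation_csv()].  Arbitrary source layouts are
#' absorbed by `column_map` (target name -> file header) and `time_unit`
#' (`"hours"` or `"days"`; day-valued schedules are converted at 24 h per
#' day).  Rows are grouped into case-level datasets by
#' site x ecosystem x substrate.
#'
#' @param path CSV file.
#' @param soils optional soil records (list from [read_soil_csv()] or a
#'   path to a soil CSV) attached to each dataset by `site/ecosystem`.
#' @param column_map optional named character vector mapping the required
#'   columns (`site`, `ecosystem`, `substrate`, `variable`, `time_h`,
#'   `value`, `replicate`) to the file's headers.
#' @param time_unit unit of the time column (default hours).
#' @return List of `incubation_data` objects.
#' @export
read_incubation_csv <- function(path, soils = NULL, column_map = NULL,
                                time_unit = c("hours", "days")) {
  time_unit <- match.arg(time_unit)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character")
  if (!is.null(column_map)) {
    miss <- setdiff(unname(column_map), names(df))
    if (length(miss)) stop("mapped column(s) absent from file: ",
                           paste(miss, collapse = ", "))
    for (target in names(column_map)) df[[target]] <- df[[column_map[[target]]]]
  }
  req <- c("site", "ecosystem", "substrate", "variable", "time_h", "value",
           "replicate")
  miss <- setdiff(req, names(df))
  if (length(miss)) stop("missing required column(s): ",
                         paste(miss, collapse = ", "))
  for (nm in c("time_h", "value", "replicate")) {
    v <- suppressWarnings(as.numeric(df[[nm]]))
    bad <- which(is.na(v) & !is.na(df[[nm]]))
    if (length(bad)) {
      stop(sprintf("non-numeric '%s' value at data line %d: '%s'",
                   nm, bad[1] + 1, df[[nm]][bad[1]]))
    }
    df[[nm]] <- v
  }
  if (time_unit == "days") df$time_h <- df$time_h * 24
  if (is.character(soils)) soils <- read_soil_csv(soils)
  key <- paste(df$site, df$ecosystem, df$substrate, sep = "/")
  lapply(split(seq_len(nrow(df)), key), function(idx) {
    sub <- df[idx, , drop = FALSE]
    co2 <- sub[sub$variable == "CO2", , drop = FALSE]
    mbc <- sub[sub$variable == "MBC", , drop = FALSE]
    if (nrow(mbc) == 0) stop("case ", key[idx[1]], " has no MBC observations")
    if (nrow(co2) == 0) stop("case ", key[idx[1]], " has no CO2 observations")
    soil <- if (!is.null(soils)) {
      soils[[paste(sub$site[1], sub$ecosystem[1], sep = "/")]]
    }
    ord_c <- order(co2$replicate, co2$time_h)
    ord_m <- order(mbc$replicate, mbc$time_h)
    structure(list(case = list(site = sub$site[1], ecosystem = sub$ecosystem[1],
                               substrate = sub$substrate[1],
                               schedule = if ("schedule" %in% names(sub))
                                 sub$schedule[1] else "custom"),
                   co2 = data.frame(time_h = co2$time_h[ord_c],
                                    rate = co2$value[ord_c],
                                    replicate = co2$replicate[ord_c]),
                   mbc = data.frame(time_h = mbc$time_h[ord_m],
                                    value = mbc$value[ord_m],
                                    replicate = mbc$replicate[ord_m]),
                   soil = soil, true_params = NULL, truncated_days = NULL),
              class = "incubation_data")
  })
}

#' Export a trajectory as tidy CSV (time, pool, value)
#' @param traj a [mend_integrate()] trajectory.
#' @param path output CSV.
#' @return `path`, invisibly.
#' @export
write_trajectory_csv <- function(traj, path) {
  long <- do.call(rbind, lapply(MEND_POOLS, function(p) {
    data.frame(time = traj$time, pool = p, value = traj[[p]])
  }))
  utils::write.csv(long, path, row.names = FALSE)
  invisible(path)
}

#' Run a configured experiment scenario
#'
#' Orchestrates the pipeline stages over a set of cases and writes CSV
#' artifacts plus a machine-readable JSON manifest (scenario, seed, config
#' hash, per-case status) into `out_dir`.  Scenarios:
#'
#' * `synth` - generate soils and noisy incubation datasets for the study
#'   design; writes `soils.csv`, `incubation.csv`, `truth.csv`.
#' * `calibrate` - calibrate each dataset read from `incubation_csv` /
#'   `soil_csv`; writes `bestfit.csv` and `archive.csv`.
#' * `project` - spin up and project warming for each row of a best-fit
#'   table (`bestfit_csv`, plus `soil_csv`); writes `projections.csv` and
#'   `projection_summary.csv` (mean +/- sd of the relative SOC change).
#' * `cofi` - feasible ensembles and intervals from `archive.csv` +
#'   `bestfit.csv`; writes `ensemble.csv`, `intervals.csv`.
#' * `sensitivity` - steady-state sensitivity sweep; writes
#'   `sensitivity.csv`.
#' * `meta` - summarize a field-warming table (`meta_csv`, or a generated
#'   one); writes `meta_summary.csv`.
#' * `duration_sweep` - calibrate truncations of one long-term dataset and
#'   report per-duration best fits and COFI interval widths; writes
#'   `duration_summary.csv`.
#'
#' A failing case is recorded in the manifest and the run continues; the
#' run errors only if every case fails.
#'
#' @param config a named list, or path to a YAML file with the same
#'   structure.  Common fields: `scenario`, `seed`; see details above for
#'   per-scenario fields.
#' @param out_dir output directory (created if absent).
#' @return The manifest, invisibly.
#' @export
run_experiment <- function(config, out_dir) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  stopifnot(is.list(config), !is.null(config$scenario))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- config$seed %||% 1L
  set.seed(seed)
  scenario <- config$scenario
  runner <- switch(scenario,
                   synth = .run_synth, calibrate = .run_calibrate,
                   project = .run_project, cofi = .run_cofi,
                   sensitivity = .run_sensitivity, meta = .run_meta,
                   duration_sweep = .run_duration_sweep,
                   stop("unknown scenario: ", scenario))
  status <- runner(config, out_dir)
  cfg_file <- tempfile(fileext = ".rds")
  saveRDS(config, cfg_file)
  manifest <- list(scenario = scenario, seed = seed,
                   config_hash = unname(tools::md5sum(cfg_file)),
                   cases = status$cases,
                   outputs = status$outputs,
                   created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  unlink(cfg_file)
  ok <- vapply(status$cases, function(x) identical(x$status, "ok"), TRUE)
  if (length(ok) && !any(ok)) {
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE)
    stop("all cases failed; see manifest.json")
  }
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}

.case_id <- function(case) paste(case$site, case$ecosystem, case$substrate, sep = "/")

.run_synth <- function(config, out_dir) {
  design <- config$design %||% study_design()
  if (!is.data.frame(design)) design <- as.data.frame(design)
  fp <- do.call(fixed_params, config$fixed_overrides %||% list())
  noise <- unlist(config$noise_cv %||% c(co2 = 0.10, mbc = 0.15))
  reps <- config$replicates %||% 3
  soils <- list()
  datasets <- list()
  truth <- list()
  cases <- list()
  for (i in seq_len(nrow(design))) {
    site <- design$site[i]; eco <- design$ecosystem[i]
    sub <- design$substrate[i]
    skey <- paste(site, eco, sep = "/")
    if (is.null(soils[[skey]])) {
      soils[[skey]] <- generate_soil(site = site, ecosystem = eco)
    }
    tp <- if (!is.null(config$true_params)) {
      do.call(microbial_params, config$true_params)
    } else {
      .draw_true_params()
    }
    schedule <- config$schedule %||%
      (if (sub == "glucose") "ST_G" else "LT_C")
    id <- paste(site, eco, sub, sep = "/")
    res <- tryCatch({
      d <- generate_incubation_dataset(soils[[skey]], tp, schedule = schedule,
                                       substrate = sub, fp = fp,
                                       noise_cv = noise, replicates = reps)
      datasets[[id]] <- d
      truth[[id]] <- data.frame(site = site, ecosystem = eco, substrate = sub,
                                 as.list(unclass(tp)))
      list(status = "ok")
    }, error = function(e) list(status = "failed", message = conditionMessage(e)))
    cases[[id]] <- c(list(case = id), res)
  }
  write_soil_csv(soils, file.path(out_dir, "soils.csv"))
  write_incubation_csv(datasets, file.path(out_dir, "incubation.csv"))
  utils::write.csv(do.call(rbind, truth), file.path(out_dir, "truth.csv"),
                   row.names = FALSE)
  list(cases = unname(cases),
       outputs = c("soils.csv", "incubation.csv", "truth.csv"))
}

#' Plausible truth draws for synthetic experiments (inside the prior box,
#' away from its edges, bracketing the reported best-fit ranges)
#' @noRd
.draw_true_params <- function() {
  microbial_params(r0 = stats::runif(1, 0.4, 0.9),
                   Vg = stats::runif(1, 0.02, 0.08),
                   alpha = stats::runif(1, 0.2, 0.4),
                   KD = stats::runif(1, 0.005, 0.1),
                   Yg = stats::runif(1, 0.25, 0.45))
}

.run_calibrate <- function(config, out_dir) {
  fp <- do.call(fixed_params, config$fixed_overrides %||% list())
  datasets <- config$datasets %||%
    read_incubation_csv(config$incubation_csv, soils = config$soil_csv)
  w1 <- config$w1 %||% 0.5
  max_evals <- config$max_evals %||% 5000
  ngs <- config$ngs %||% 4
  seed <- config$seed %||% 1L
  best <- list(); arch <- list(); cases <- list()
  for (i in seq_along(datasets)) {
    d <- datasets[[i]]
    id <- .case_id(d$case)
    res <- tryCatch({
      fit <- calibrate_case(d, fp, w1 = w1, ngs = ngs, max_evals = max_evals,
                            seed = seed + i)
      crit <- check_fit_criteria(fit)
      best[[id]] <- data.frame(site = d$case$site, ecosystem = d$case$ecosystem,
                                substrate = d$case$substrate,
                                as.list(unclass(fit$par)),
                                Jopt = fit$Jopt, J1 = fit$J1, J2 = fit$J2,
                                co2_metric = fit$co2_metric,
                                n_obs = fit$n_obs,
                                fit_ok = all(crit$pass))
      arch[[id]] <- cbind(case = id, fit$archive)
      list(status = "ok")
    }, error = function(e) list(status = "failed", message = conditionMessage(e)))
    cases[[id]] <- c(list(case = id), res)
  }
  if (length(best)) {
    utils::write.csv(do.call(rbind, best), file.path(out_dir, "bestfit.csv"),
                     row.names = FALSE)
    utils::write.csv(do.call(rbind, arch), file.path(out_dir, "archive.csv"),
                     row.names = FALSE)
  }
  list(cases = unname(cases), outputs = c("bestfit.csv", "archive.csv"))
}

.run_project <- function(config, out_dir) {
  fp <- do.call(fixed_params, config$fixed_overrides %||% list())
  best <- utils::read.csv(config$bestfit_csv, stringsAsFactors = FALSE)
  soils <- read_soil_csv(config$soil_csv)
  dT <- config$dT %||% 5
  years <- config$years %||% 50
  rows <- list(); cases <- list()
  for (i in seq_len(nrow(best))) {
    id <- paste(best$site[i], best$ecosystem[i], best$substrate[i], sep = "/")
    res <- tryCatch({
      mp <- microbial_params(best$r0[i], best$Vg[i], best$alpha[i],
                             best$KD[i], best$Yg[i])
      soil <- soils[[paste(best$site[i], best$ecosystem[i], sep = "/")]]
      st <- spin_up(soil, mp, fp, T = fp$Tref)
      pr <- project_warming(st, mp, fp, dT = dT, years = years)
      rows[[id]] <- data.frame(site = best$site[i], ecosystem = best$ecosystem[i],
                                substrate = best$substrate[i],
                                baseline_soc = pr$baseline_soc,
                                warmed_soc = pr$warmed_soc,
                                rel_change_pct = pr$rel_change_pct)
      list(status = "ok")
    }, error = function(e) list(status = "failed", message = conditionMessage(e)))
    cases[[id]] <- c(list(case = id), res)
  }
  if (length(rows)) {
    proj <- do.call(rbind, rows)
    utils::write.csv(proj, file.path(out_dir, "projections.csv"),
                     row.names = FALSE)
    summ <- data.frame(dT = dT, years = years, n = nrow(proj),
                       mean_rel_change_pct = mean(proj$rel_change_pct),
                       sd_rel_change_pct = stats::sd(proj$rel_change_pct))
    utils::write.csv(summ, file.path(out_dir, "projection_summary.csv"),
                     row.names = FALSE)
  }
  list(cases = unname(cases),
       outputs = c("projections.csv", "projection_summary.csv"))
}

.run_cofi <- function(config, out_dir) {
  arch <- utils::read.csv(config$archive_csv, stringsAsFactors = FALSE)
  best <- utils::read.csv(config$bestfit_csv, stringsAsFactors = FALSE)
  p <- config$p %||% 5
  alpha <- config$alpha %||% 0.05
  ens <- list(); ints <- list(); cases <- list()
  for (i in seq_len(nrow(best))) {
    id <- paste(best$site[i], best$ecosystem[i], best$substrate[i], sep = "/")
    res <- tryCatch({
      a <- arch[arch$case == id, setdiff(names(arch), "case"), drop = FALSE]
      jcr <- cofi_threshold(best$Jopt[i], n = best$n_obs[i], p = p, alpha = alpha)
      fe <- feasible_ensemble(a, jcr)
      ens[[id]] <- cbind(case = id, as.data.frame(fe))
      iv <- cofi_intervals(fe)
      ints[[id]] <- cbind(case = id, Jcr = jcr, iv)
      list(status = "ok")
    }, error = function(e) list(status = "failed", message = conditionMessage(e)))
    cases[[id]] <- c(list(case = id), res)
  }
  if (length(ens)) {
    utils::write.csv(do.call(rbind, ens), file.path(out_dir, "ensemble.csv"),
                     row.names = FALSE)
    utils::write.csv(do.call(rbind, ints), file.path(out_dir, "intervals.csv"),
                     row.names = FALSE)
  }
  list(cases = unname(cases), outputs = c("ensemble.csv", "intervals.csv"))
}

.run_sensitivity <- function(config, out_dir) {
  fp <- do.call(fixed_params, config$fixed_overrides %||% list())
  soil <- if (!is.null(config$soil_seed)) generate_soil(seed = config$soil_seed)
  sens <- sensitivity_sweep(fp = fp, soil = soil)
  utils::write.csv(sens, file.path(out_dir, "sensitivity.csv"), row.names = FALSE)
  list(cases = list(list(case = "sensitivity", status = "ok")),
       outputs = "sensitivity.csv")
}

.run_meta <- function(config, out_dir) {
  obs <- if (!is.null(config$meta_csv)) {
    read_meta_csv(config$meta_csv, column_map = config$column_map)
  } else {
    generate_meta_table(seed = config$seed %||% 1L)
  }
  s <- summarize_effects(obs, mode = config$mode %||% "percent")
  out <- rbind(s$by_bin,
               data.frame(bin = "all", mean = s$overall$mean,
                          sd = s$overall$sd, n = s$overall$n))
  utils::write.csv(out, file.path(out_dir, "meta_summary.csv"), row.names = FALSE)
  list(cases = list(list(case = "meta", status = "ok")),
       outputs = "meta_summary.csv")
}

.run_duration_sweep <- function(config, out_dir) {
  fp <- do.call(fixed_params, config$fixed_overrides %||% list())
  durations <- config$durations %||% c(6, 30, 90, 180, 360, 480, 729)
  dataset <- config$dataset
  if (is.null(dataset)) {
    soil <- generate_soil(seed = config$seed %||% 1L)
    dataset <- generate_incubation_dataset(soil, .draw_true_params(),
                                           schedule = "LT_C", fp = fp)
  }
  w1 <- config$w1 %||% 0.5
  max_evals <- config$max_evals %||% 5000
  rows <- list(); cases <- list()
  for (d in durations) {
    id <- sprintf("%gd", d)
    res <- tryCatch({
      td <- truncate_dataset(dataset, d)
      fit <- calibrate_case(td, fp, w1 = w1, max_evals = max_evals,
                            seed = (config$seed %||% 1L) + round(d))
      jcr <- cofi_threshold(fit$Jopt, n = fit$n_obs, p = 5)
      iv <- cofi_intervals(feasible_ensemble(fit$archive, jcr))
      rows[[id]] <- data.frame(duration_d = d, as.list(unclass(fit$par)),
                                Jopt = fit$Jopt, n_obs = fit$n_obs,
                                KD_width = iv$width[iv$parameter == "KD"],
                                Yg_width = iv$width[iv$parameter == "Yg"])
      list(status = "ok")
    }, error = function(e) list(status = "failed", message = conditionMessage(e)))
    cases[[id]] <- c(list(case = id), res)
  }
  if (length(rows)) {
    utils::write.csv(do.call(rbind, rows),
                     file.path(out_dir, "duration_summary.csv"),
                     row.names = FALSE)
  }
  list(cases = unname(cases), outputs = "duration_summary.csv")
}
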