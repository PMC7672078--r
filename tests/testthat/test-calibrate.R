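test_that("MARE matches hand-computed sums and guards its domain", {
  expect_equal(mare(c(1, 2, 4), c(1, 2, 4)), 0)
  expect_equal(mare(c(1, 2, 4), c(2, 1, 2)), (1 + 0.5 + 0.5) / 3,
               tolerance = 1e-12)
  expect_equal(mare(10, 15), 0.5)
  expect_error(mare(c(0, 1), c(1, 1)), "zero")
  expect_error(mare(1:3, 1:2), "length")
})

test_that("R^2 matches its definition including degenerate cases", {
  expect_equal(r_squared(c(1, 2, 3), c(1, 2, 3)), 1)
  expect_equal(r_squared(c(1, 2, 3), rep(2, 3)), 0)   # null model
  expect_equal(r_squared(c(1, 2, 3), c(1.1, 1.9, 3.2)), 1 - 0.06 / 2,
               tolerance = 1e-12)
  expect_error(r_squared(c(2, 2, 2), c(1, 2, 3)), "constant")
  expect_error(r_squared(1, 1), "two")
  # worse than the mean: negative, still <= 1
  expect_lt(r_squared(c(1, 2, 3), c(5, -4, 9)), 0)
})

test_that("objective applies the metric rule by series length and the weights", {
  soil <- test_soil(8)
  truth <- microbial_params(0.6, 0.04, 0.3, 0.02, 0.32)
  st <- generate_incubation_dataset(soil, truth, schedule = "ST_G",
                                    noise_cv = c(co2 = 0.05, mbc = 0.05),
                                    seed = 21)
  lt <- generate_incubation_dataset(soil, truth, schedule = "LT_C",
                                    noise_cv = c(co2 = 0.05, mbc = 0.05),
                                    seed = 22)
  mp <- microbial_defaults()
  Js <- incubation_objective(mp, st, fp_default)
  Jl <- incubation_objective(mp, lt, fp_default)
  expect_identical(attr(Js, "co2_metric"), "mare")          # 7 points  -> MARE
  expect_identical(attr(Jl, "co2_metric"), "one_minus_r2")  # 18 points -> 1-R^2
  expect_equal(as.numeric(Js),
               0.5 * attr(Js, "J1") + 0.5 * attr(Js, "J2"), tolerance = 1e-12)
  J1only <- incubation_objective(mp, st, fp_default, w1 = 1)
  expect_equal(as.numeric(J1only), attr(Js, "J1"), tolerance = 1e-12)
  expect_error(incubation_objective(mp, st, fp_default, w1 = 1.5), "w1")

  # objective is invariant to observation ordering
  shuf <- st
  set.seed(1)
  shuf$co2 <- shuf$co2[sample(nrow(shuf$co2)), ]
  shuf$mbc <- shuf$mbc[sample(nrow(shuf$mbc)), ]
  expect_equal(as.numeric(incubation_objective(mp, shuf, fp_default)),
               as.numeric(Js), tolerance = 1e-12)
})

test_that("SCE-UA solves a five-dimensional sphere and is reproducible", {
  sphere <- function(x) sum(x^2)
  b <- rbind(lo = rep(-5, 5), hi = rep(5, 5))
  colnames(b) <- paste0("x", 1:5)
  r1 <- sce_optimize(sphere, b, seed = 1)
  expect_lt(r1$value, 1e-4)
  expect_true(all(abs(r1$par) < 0.05))
  r2 <- sce_optimize(sphere, b, seed = 1)
  expect_identical(r1$archive, r2$archive)   # same seed, same path
  r3 <- sce_optimize(sphere, b, seed = 2)
  expect_false(identical(r1$archive, r3$archive))

  # never leaves the box; Jopt equals the archive minimum
  expect_true(all(apply(r1$archive[paste0("x", 1:5)], 1,
                        function(x) all(x >= -5 & x <= 5))))
  expect_equal(r1$value, min(r1$archive$J))
  expect_error(sce_optimize(sphere, b, ngs = 1), "complexes")
})

test_that("failed simulations score +Inf instead of aborting", {
  soil <- test_soil(8)
  d <- generate_incubation_dataset(soil, microbial_defaults(), schedule = "ST_G",
                                   noise_cv = c(co2 = 0, mbc = 0),
                                   replicates = 1)
  d$soil$soc <- NaN   # poisoned case: simulation cannot start
  expect_identical(as.numeric(suppressWarnings(
    incubation_objective(microbial_defaults(), d, fp_default))), Inf)
})

test_that("noise-free self-consistency: calibration recovers the exact truth", {
  soil <- test_soil(5)
  truth <- microbial_params(0.6, 0.04, 0.3, 0.02, 0.32)
  d <- generate_incubation_dataset(soil, truth, schedule = "LT_C",
                                   noise_cv = c(co2 = 0, mbc = 0),
                                   replicates = 1)
  fit <- calibrate_case(d, fp_default, max_evals = 8000, seed = 4)
  expect_lt(fit$Jopt, 1e-3)
  tv <- unlist(unclass(truth))
  fv <- unlist(unclass(fit$par))
  expect_true(all(abs(fv - tv) / tv < 0.02))
  expect_true(fit$converged)
})

test_that("fit criteria gate MARE at 0.5 and R^2 at 0.6 inclusively", {
  mk <- function(J1, J2, metric) {
    structure(list(J1 = J1, J2 = J2, co2_metric = metric),
              class = "calibration_result")
  }
  crit <- check_fit_criteria(mk(0.5, 0.3, "mare"))
  expect_true(all(crit$pass))             # MARE = 0.5 exactly passes
  crit <- check_fit_criteria(mk(0.51, 0.3, "mare"))
  expect_false(crit$pass[crit$component == "CO2"])
  crit <- check_fit_criteria(mk(1 - 0.55, 0.2, "one_minus_r2"))
  expect_false(crit$pass[crit$component == "CO2"])  # R^2 = 0.55 < 0.6
  expect_equal(crit$value[crit$component == "CO2"], 0.55)
  crit <- check_fit_criteria(mk(1 - 0.6, 0.5, "one_minus_r2"))
  expect_true(all(crit$pass))             # both boundaries inclusive
  crit <- check_fit_criteria(mk(0.2, 0.7, "mare"))
  expect_false(crit$pass[crit$component == "MBC"])
})
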