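test_that("closed-system trajectories conserve total carbon", {
  soil <- test_soil(2)
  mp <- mp_ref
  s0 <- soil_state0(soil, mp, "cellulose")
  env <- mend_env(T = 22)
  times <- c(0, 24 * c(1, 5, 30, 180, 729))
  traj <- mend_integrate(s0, mp, fp_default, env, times)
  tot <- rowSums(traj[, setdiff(MEND_POOLS, "CO2")]) + traj$CO2
  expect_lt(max(abs(tot - tot[1])) / tot[1], 1e-6)
})

test_that("trajectories with external inputs balance carbon against inputs", {
  soil <- test_soil(2)
  env <- mend_env(T = 20, IP1 = 4e-5, IP2 = 4e-5, ID = 2e-5)
  s0 <- soil_state0(soil, mp_ref, "none")
  times <- seq(0, 8760 * 5, length.out = 11)
  traj <- mend_integrate(s0, mp_ref, fp_default, env, times)
  tot <- rowSums(traj[, setdiff(MEND_POOLS, "CO2")]) + traj$CO2
  expected <- tot[1] + (env$IP1 + env$IP2 + env$ID) * times
  expect_lt(max(abs(tot - expected)) / tot[1], 1e-6)
})

test_that("integration is deterministic and robust to tolerance refinement", {
  soil <- test_soil(4)
  s0 <- soil_state0(soil, mp_ref, "glucose")
  env <- mend_env(T = 22)
  times <- c(0, 2, 24, 144)
  a <- mend_integrate(s0, mp_ref, fp_default, env, times)
  b <- mend_integrate(s0, mp_ref, fp_default, env, times)
  expect_identical(a, b)
  fine <- mend_integrate(s0, mp_ref, fp_default, env, times,
                         rtol = 5e-9, atol = 5e-11)
  soc_end <- sum(a[nrow(a), setdiff(MEND_POOLS, "CO2")])
  soc_fine <- sum(fine[nrow(fine), setdiff(MEND_POOLS, "CO2")])
  expect_lt(abs(soc_end - soc_fine) / soc_fine, 1e-5)
  expect_error(mend_integrate(s0, mp_ref, fp_default, env, c(0, 24, 12)),
               "increasing")
})

test_that("incubation runs honour the declared collection schedules", {
  soil <- test_soil(1)
  st <- run_incubation(soil, mp_ref, fp_default, "glucose", "ST_G")
  expect_equal(st$co2$time_h, c(2, 4, 8, 24, 48, 72, 144))
  expect_equal(st$mbc$time_h, c(24, 72, 144))
  lt <- run_incubation(soil, mp_ref, fp_default, "cellulose", "LT_C")
  expect_equal(nrow(lt$co2), 18)
  expect_equal(nrow(lt$mbc), 8)
  expect_equal(max(lt$co2$time_h), 729 * 24)
})

test_that("substrate pulses are routed to the right pool and respire", {
  soil <- test_soil(1)
  s_glu <- soil_state0(soil, mp_ref, "glucose")
  s_cel <- soil_state0(soil, mp_ref, "cellulose")
  s_non <- soil_state0(soil, mp_ref, "none")
  expect_equal(s_glu[["D"]] - s_non[["D"]], 0.01 * soil$soc)
  expect_equal(s_cel[["P2"]] - s_non[["P2"]], 0.01 * soil$soc)
  mp1 <- microbial_params(1, mp_ref$Vg, mp_ref$alpha, mp_ref$KD, mp_ref$Yg)
  expect_equal(soil_state0(soil, mp1, "none")[["BD"]], 0)

  glu <- run_incubation(soil, mp_ref, fp_default, "glucose", "ST_G")
  non <- run_incubation(soil, mp_ref, fp_default, "none", "ST_G")
  cum <- function(x) sum(x$co2$rate * diff(c(0, x$co2$time_h)))
  expect_gt(cum(glu), cum(non))
})

test_that("spin-up reaches a genuine, unique steady state", {
  soil <- test_soil(6)
  st <- spin_up(soil, mp_ref, fp_default, T = 20, tol = 1e-9)
  env <- attr(st, "env")
  d <- mend_rhs(st, mp_ref, fp_default, env)[1:10]
  expect_lt(max(abs(d) / pmax(unclass(st)[1:10], 1e-8)), 1e-9)
  expect_true(all(unclass(st) >= 0))

  # doubling the input rate strictly increases steady SOC
  st2 <- spin_up(soil, mp_ref, fp_default, T = 20, input_frac = 0.10)
  expect_gt(soc(st2), soc(st))

  # convergence from a very different initial state
  far <- pool_state(P1 = 30, P2 = 1, M = 2, D = 1, Q = 0.5, BA = 0.5,
                    BD = 0.01, EP1 = 0.01, EP2 = 0.01, EM = 0.01)
  st3 <- spin_up(soil, mp_ref, fp_default, T = 20, state0 = far)
  expect_equal(unclass(st3)[1:10], unclass(st)[1:10], tolerance = 1e-6)
})

test_that("projection from steady state is flat without warming", {
  soil <- test_soil(6)
  st <- spin_up(soil, mp_ref, fp_default, T = 20)
  pr0 <- project_warming(st, mp_ref, fp_default, dT = 0, years = 50)
  expect_lt(abs(pr0$rel_change_pct), 1e-6)
  # steady-state fixed point: baseline SOC stays put over five decades
  expect_lt(abs(pr0$baseline_soc - soc(st)) / soc(st), 1e-4)
})

test_that("warming response switches sign across the CUE threshold", {
  soil <- test_soil(1)
  lo <- microbial_params(mp_ref$r0, mp_ref$Vg, mp_ref$alpha, mp_ref$KD, 0.30)
  hi <- microbial_params(mp_ref$r0, mp_ref$Vg, mp_ref$alpha, mp_ref$KD, 0.40)
  st_lo <- spin_up(soil, lo, fp_default, T = 20)
  st_hi <- spin_up(soil, hi, fp_default, T = 20)
  pr_lo <- project_warming(st_lo, lo, fp_default, dT = 5, years = 50)
  pr_hi <- project_warming(st_hi, hi, fp_default, dT = 5, years = 50)
  expect_gt(pr_lo$rel_change_pct, 0)   # low CUE: warming gains carbon
  expect_lt(pr_hi$rel_change_pct, 0)   # high CUE: warming loses carbon
})
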