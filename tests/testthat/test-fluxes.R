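test_that("derivatives conserve carbon for arbitrary states and parameters", {
  set.seed(7)
  for (i in 1:50) {
    st <- random_state(); mp <- random_mp(); env <- random_env()
    d <- mend_rhs(st, mp, fp_default, env)
    imbalance <- sum(d) - (env$IP1 + env$IP2 + env$ID)
    scale <- max(sum(abs(d)), 1e-12)
    expect_lt(abs(imbalance) / scale, 1e-12)
  }
})

test_that("all pools zero gives zero derivatives except direct inputs", {
  z <- pool_state()
  mp <- mp_ref
  expect_true(all(mend_rhs(z, mp, fp_default, mend_env()) == 0))
  d <- mend_rhs(z, mp, fp_default, mend_env(ID = 1e-4))
  expect_equal(unname(d["D"]), 1e-4)
  expect_true(all(d[setdiff(names(d), "D")] == 0))
})

test_that("flux forms have the right substrate limits", {
  mp <- mp_ref; env <- mend_env(T = 22)
  base <- pool_state(P1 = 3, P2 = 4, M = 15, D = 0, Q = 0.1, BA = 0.1,
                     BD = 0.2, EP1 = 1e-3, EP2 = 1e-3, EM = 1e-3)
  f0 <- compute_fluxes(base, mp, fp_default, env)
  # zero DOC: no uptake, no reactivation, dormancy at the full maintenance rate
  expect_equal(unname(f0["uptake"]), 0)
  expect_equal(unname(f0["reactivation"]), 0)
  Vmt_T <- derived_maintenance_rate(mp$Vg, mp$alpha) *
    arrhenius_factor(fp_default$Ea_V, 22, fp_default$Tref)
  expect_equal(unname(f0["dormancy"]), Vmt_T * 0.1, tolerance = 1e-12)

  # saturated sorbent: no further adsorption
  sat <- base; sat["D"] <- 0.05; sat["Q"] <- fp_default$Qmax
  expect_equal(unname(compute_fluxes(sat, mp, fp_default, env)["adsorption"]), 0)

  # Michaelis-Menten saturation: uptake approaches (Vg+Vmt)/Yg * BA
  rich <- base; rich["D"] <- 1e4 * mp$KD
  fr <- compute_fluxes(rich, mp, fp_default, env)
  Yg_T <- yg_at_temperature(mp$Yg, fp_default$kYg, 22, fp_default$Tref)
  Vg_T <- mp$Vg * arrhenius_factor(fp_default$Ea_V, 22, fp_default$Tref)
  expect_equal(unname(fr["uptake"]), (Vg_T + Vmt_T) / Yg_T * 0.1,
               tolerance = 1e-3)

  expect_error(compute_fluxes(replace(unclass(base), 1, -1), mp, fp_default, env),
               "negative")
})

test_that("every flux out of a pool vanishes as the pool empties", {
  mp <- mp_ref; env <- mend_env(T = 22)
  full <- pool_state(P1 = 3, P2 = 4, M = 15, D = 0.2, Q = 0.1, BA = 0.1,
                     BD = 0.2, EP1 = 1e-3, EP2 = 1e-3, EM = 1e-3)
  drains <- list(P1 = "dec_P1", P2 = "dec_P2", M = "dec_M", D = "uptake",
                 Q = "desorption", BA = "mortality", BD = "reactivation",
                 EP1 = "eturn_P1", EP2 = "eturn_P2", EM = "eturn_M")
  for (pool in names(drains)) {
    st <- unclass(full); st[pool] <- 0
    f <- compute_fluxes(st, mp, fp_default, env)
    expect_equal(unname(f[drains[[pool]]]), 0,
                 info = paste("drain of", pool))
  }
})

test_that("V-type rates increase strictly with temperature", {
  mp <- mp_ref
  st <- pool_state(P1 = 3, P2 = 4, M = 15, D = 0.2, Q = 0.1, BA = 0.1,
                   BD = 0.2, EP1 = 1e-3, EP2 = 1e-3, EM = 1e-3)
  dec <- sapply(c(10, 15, 20, 25, 30), function(T) {
    compute_fluxes(st, mp, fp_default, mend_env(T = T))[c("dec_P1", "dec_M")]
  })
  expect_true(all(diff(t(dec)) > 0))
})

test_that("compiled RHS agrees with the R reference over a trajectory", {
  soil <- test_soil(3)
  mp <- mp_ref
  env <- mend_env(T = 22)
  s0 <- soil_state0(soil, mp, "glucose")
  times <- c(0, 2, 8, 24, 72, 144)
  a <- mend_integrate(s0, mp, fp_default, env, times, compiled = TRUE)
  b <- mend_integrate(s0, mp, fp_default, env, times, compiled = FALSE)
  for (p in MEND_POOLS) {
    expect_equal(a[[p]], b[[p]], tolerance = 1e-6)
  }
  # and pointwise at states visited: identical derivative vectors
  pv <- mendfusion:::mend_parms_vector(mp, fp_default, env)
  set.seed(11)
  for (i in 1:10) {
    y <- mendfusion:::.as_state(random_state())
    expect_equal(sum(mendfusion:::.mend_rhs_pv(y, pv)) -
                   (env$IP1 + env$IP2 + env$ID), 0, tolerance = 1e-15)
  }
})
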