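test_that("generated soils are reproducible, in range, and sum to SOC", {
  s1 <- generate_soil(seed = 10)
  s2 <- generate_soil(seed = 10)
  expect_identical(unclass(s1), unclass(s2))

  rng <- soil_ranges()
  set.seed(99)
  for (i in 1:1000) {
    s <- generate_soil()
    total <- s$poc1 + s$poc2 + s$moc + s$doc + s$mbc
    expect_lt(abs(total - s$soc), 1e-9)
    expect_true(s$soc >= rng$soc[1] && s$soc <= rng$soc[2])
    expect_true(s$mbc / s$soc >= rng$mbc_frac[1] &&
                  s$mbc / s$soc <= rng$mbc_frac[2])
    expect_true(s$doc / s$soc >= rng$doc_frac[1] &&
                  s$doc / s$soc <= rng$doc_frac[2])
    expect_true(s$moc / s$soc >= rng$moc_frac[1] &&
                  s$moc / s$soc <= rng$moc_frac[2])
    expect_equal(s$poc2 / s$poc1, 2, tolerance = 1e-9)
  }
  expect_error(generate_soil(ranges = list(soc = c(60, 10))), "infeasible")
})

test_that("noise-free single-replicate dataset equals the forward simulation", {
  soil <- test_soil(3)
  truth <- microbial_defaults()
  d <- generate_incubation_dataset(soil, truth, schedule = "LT_C",
                                   noise_cv = c(co2 = 0, mbc = 0),
                                   replicates = 1)
  sim <- run_incubation(soil, truth, fp_default, "cellulose", "LT_C",
                        check_balance = FALSE)
  expect_equal(d$co2$rate, sim$co2$rate, tolerance = 1e-12)
  expect_equal(d$mbc$value, sim$mbc$value, tolerance = 1e-12)
  expect_equal(length(unique(d$co2$time_h)), 18)
  expect_equal(length(unique(d$mbc$time_h)), 8)
  expect_identical(d$case$substrate, "cellulose")
})

test_that("noisy datasets are seed-reproducible with positive values", {
  soil <- test_soil(3)
  d1 <- generate_incubation_dataset(soil, microbial_defaults(), seed = 5)
  d2 <- generate_incubation_dataset(soil, microbial_defaults(), seed = 5)
  expect_identical(d1$co2, d2$co2)
  expect_identical(d1$mbc, d2$mbc)
  expect_true(all(d1$co2$rate > 0))
  expect_true(all(d1$mbc$value > 0))
  expect_equal(nrow(d1$co2), 18 * 3)   # three replicates by default
  d3 <- generate_incubation_dataset(soil, microbial_defaults(), seed = 6)
  expect_false(identical(d1$co2, d3$co2))
})

test_that("truncation filters the printed schedule correctly", {
  soil <- test_soil(3)
  d <- generate_incubation_dataset(soil, microbial_defaults(), schedule = "LT_C",
                                   noise_cv = c(co2 = 0, mbc = 0),
                                   replicates = 1)
  t30 <- truncate_dataset(d, 30)
  expect_equal(t30$co2$time_h / 24, c(1, 2, 4, 6, 11, 20))
  expect_equal(t30$mbc$time_h / 24, c(1, 4, 20))
  expect_equal(t30$truncated_days, 30)

  full <- truncate_dataset(d, 729)
  expect_equal(full$co2, d$co2)
  expect_equal(full$mbc, d$mbc)

  expect_error(truncate_dataset(d, 0.5), "both CO2 and MBC")
  expect_error(truncate_dataset(d, 1000), "exceeds")
})

test_that("synthetic meta tables honour the group design", {
  exact <- generate_meta_table(list("<1" = c(mean = -4.8, sd = 0, n = 5),
                                    "1-10" = c(mean = 1.4, sd = 0, n = 7),
                                    ">10" = c(mean = 2.8, sd = 0, n = 3)),
                               seed = 1)
  expect_equal(nrow(exact), 15)
  s <- summarize_effects(exact)
  expect_equal(s$by_bin$mean, c(-4.8, 1.4, 2.8), tolerance = 1e-9)
  expect_equal(s$by_bin$n, c(5, 7, 3))

  tab <- generate_meta_table(seed = 3)
  expect_equal(nrow(tab), 149)          # default design size
  expect_true(all(tab$soc_control > 0 & tab$soc_warmed > 0))
  expect_true(all(tab$delta_t >= 1 & tab$delta_t <= 5))
  # recovered group means within twice the standard error of the truth
  s2 <- summarize_effects(tab)
  spec <- meta_group_defaults()
  for (b in names(spec)) {
    se <- spec[[b]][["sd"]] / sqrt(spec[[b]][["n"]])
    expect_lt(abs(s2$by_bin$mean[s2$by_bin$bin == b] - spec[[b]][["mean"]]),
              2 * se + 1e-12)
  }
  expect_error(generate_meta_table(list("<1" = c(mean = 0, sd = -1, n = 2))),
               "sd")
})

test_that("the full study design has 16 cases", {
  d <- study_design()
  expect_equal(nrow(d), 16)
  expect_equal(length(unique(d$site)), 4)
  expect_equal(nrow(unique(d[c("ecosystem", "substrate")])), 4)
})
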