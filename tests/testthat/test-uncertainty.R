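test_that("COFI threshold matches the F-quantile formula", {
  expect_identical(cofi_threshold(0, n = 25, p = 5), 0)
  # independent oracle: F(0.05, 5, 20) = 2.7108898 (tabulated)
  expect_equal(cofi_threshold(0.2, n = 25, p = 5),
               0.2 * (1 + 5 / 20 * 2.7108898), tolerance = 1e-6)
  expect_equal(cofi_threshold(0.2, n = 25, p = 5), 0.33554, tolerance = 1e-4)
  # large-n limit: threshold collapses onto the optimum
  expect_equal(cofi_threshold(0.2, n = 1e6, p = 5) / 0.2, 1, tolerance = 1e-4)
  expect_error(cofi_threshold(0.2, n = 5, p = 5), "n > p")
  expect_gte(cofi_threshold(0.3, n = 26, p = 5), 0.3)
  # strictly decreasing in n for fixed Jopt, p
  ns <- c(10, 20, 50, 200, 1000)
  jcr <- sapply(ns, function(n) cofi_threshold(0.2, n, 5))
  expect_true(all(diff(jcr) < 0))
})

test_that("feasible ensemble equals a brute-force filter of the archive", {
  set.seed(13)
  archive <- data.frame(r0 = runif(1000), Vg = runif(1000), J = rexp(1000))
  jcr <- quantile(archive$J, 0.3)
  fe <- feasible_ensemble(archive, jcr)
  brute <- archive[sapply(archive$J, function(j) j <= jcr), ]
  expect_equal(nrow(fe), nrow(brute))
  expect_equal(fe$J, brute$J)
  expect_equal(fe$r0, brute$r0)
  # boundary cases
  expect_warning(empty <- feasible_ensemble(archive, min(archive$J) - 1),
                 "empty")
  expect_equal(nrow(empty), 0)
  expect_equal(nrow(feasible_ensemble(archive, Inf)), 1000)
  iv <- cofi_intervals(fe)
  expect_equal(iv$width, iv$hi - iv$lo)
})

test_that("Kruskal-Wallis comparison matches hand-computed ranks", {
  # A = {1,3,5}, B = {2,4,6}: ranks 1..6, no ties;
  # H = 12/(6*7) * (3*(3-3.5)^2 + 3*(4-3.5)^2) = 3/7
  ensA <- data.frame(x = c(1, 3, 5))
  ensB <- data.frame(x = c(2, 4, 6))
  out <- kruskal_wallis_compare(ensA, ensB)
  expect_equal(out$statistic, 3 / 7, tolerance = 1e-12)
  expect_false(out$significant)

  ident <- data.frame(x = rep(2, 5))
  out2 <- kruskal_wallis_compare(ident, ident)
  expect_equal(out2$p_value, 1)

  # total rank separation of two large groups
  set.seed(3)
  big <- kruskal_wallis_compare(data.frame(x = runif(100, 0, 0.1)),
                                data.frame(x = runif(100, 0.9, 1)))
  expect_lt(big$p_value, 1e-10)
  expect_true(big$significant)
  expect_error(kruskal_wallis_compare(data.frame(x = 1), ensB), ">= 2")
})

test_that("paired t comparison reproduces the textbook statistic", {
  short <- c(2, 4, 3.5, 5, 4)
  long <- c(1, 2, 3, 3.5, 3)
  d <- short - long                       # 1, 2, 0.5, 1.5, 1
  t_manual <- mean(d) / sqrt(sum((d - mean(d))^2) / 4 / 5)
  out <- paired_t_compare(short, long)
  expect_equal(out$t, t_manual, tolerance = 1e-12)
  expect_equal(out$n_short_higher, 5)
  expect_false(out$degenerate)

  same <- paired_t_compare(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$t, 0)
  expect_equal(same$p_value, 1)
  expect_true(same$degenerate)

  set.seed(9)
  jit <- paired_t_compare(1:8 + 1 + rnorm(8, 0, 1e-3), 1:8)
  expect_lt(jit$p_value, 1e-6)
  expect_error(paired_t_compare(1:3, 1:4), "paired")
})

test_that("sensitivity index counts decades and ignores labels", {
  expect_equal(sensitivity_index(5, 5, 0.1, 10), 0)
  expect_equal(sensitivity_index(100, 1, 10, 0.1), 1)
  expect_equal(sensitivity_index(1000, 10, 10, 1), 2)
  # swap either axis: unchanged
  expect_equal(sensitivity_index(1, 100, 10, 0.1), 1)
  expect_equal(sensitivity_index(100, 1, 0.1, 10), 1)
  expect_error(sensitivity_index(0, 1, 1, 2), "nonzero")
  expect_error(sensitivity_index(1, 2, 3, 3), "differ")
})

test_that("steady-state SOC is most sensitive to CUE among r0, Vg, KD", {
  sens <- sensitivity_sweep(soil = test_soil(1))
  si_soc <- setNames(sens$SOC, sens$parameter)
  expect_gt(si_soc["Yg"], si_soc["r0"])
  expect_gt(si_soc["Yg"], si_soc["Vg"])
  expect_gt(si_soc["Yg"], si_soc["KD"])
  # the initial active fraction cannot move a steady state
  expect_lt(si_soc["r0"], 1e-6)
})
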