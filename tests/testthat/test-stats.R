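test_that("marginal probabilities reproduce the worked example", {
  expect_equal(marginal_probability(243, 905), 243 / 905)
  expect_equal(round_like_paper(marginal_probability(243, 905), sig = 3,
                                method = "truncate"), 0.268)
  expect_equal(round_like_paper(marginal_probability(578, 1622)), 0.36)
  expect_equal(marginal_probability(0, 100), 0)
  expect_error(marginal_probability(120, 100), "exceeds")
})

test_that("display rounding follows the published conventions", {
  expect_equal(round_like_paper(0.02856), 0.029)
  expect_equal(round_like_paper(0.5), 0.5)
  expect_equal(round_like_paper(0.002578), 0.0026)
  expect_equal(round_like_paper(0.26851, sig = 3, method = "truncate"), 0.268)
  expect_equal(round_like_paper(c(0, 0.117127)), c(0, 0.12))
  # the worked example's product prints as 0.03 at two decimals
  expect_true(iftcargo:::matches_printed(0.268508 * 0.117127, "0.03"))
})

test_that("cotransport analysis reproduces the published derived values", {
  fit <- cotransport_test(count_record("regen", 578, 130, 104, 1622),
                          method = "none")
  expect_equal(fit$p_obs, 104 / 1622)
  expect_equal(fit$p_calc, (578 / 1622) * (130 / 1622))
  expect_equal(fit$frac_b_with_a, 0.8)
  expect_equal(round(100 * fit$frac_a_solo), 82)

  fit2 <- cotransport_test(count_record("oda", 82, 78, 3, 1575),
                           method = "none")
  expect_equal(round_like_paper(fit2$p_obs), 0.0019)
  expect_equal(round_like_paper(fit2$p_calc), 0.0026)
})

test_that("degenerate counts are handled explicitly", {
  fit <- cotransport_test(count_record("none", 10, 0, 0, 100), method = "none")
  expect_true(is.na(fit$frac_b_with_a))   # absent, not zero
  expect_equal(fit$p_obs, 0)
  expect_equal(as.numeric(independence_test(count_record("x", 0, 5, 0, 100))), 1)
  expect_error(count_record("bad", 5, 3, 4, 100), "n_co")
  expect_error(count_record("toolong", 200, 3, 1, 100), "train count")
})

test_that("analysis is invariant to rescaling counts and duration together", {
  base <- cotransport_test(count_record("b", 57, 13, 10, 162), method = "none")
  for (k in c(2, 5)) {
    sc <- cotransport_test(count_record("s", 57 * k, 13 * k, 10 * k, 162 * k),
                           method = "none")
    expect_equal(coef(sc), coef(base))
  }
})

test_that("the exact test matches hand enumeration on a tiny table", {
  rec <- count_record("tiny", 2, 2, 2, duration = 4)
  expect_equal(as.numeric(independence_test(rec, alternative = "greater")),
               1 / 6)
})

test_that("permutation and exact p-values agree with full enumeration on small tables", {
  rec <- count_record("small", 12, 10, 6, duration = 40)
  # enumeration oracle for the permutation statistic |nCo - E|
  N <- 40; ex <- 12 * 10 / N
  k <- 0:10
  pr <- stats::dhyper(k, 12, N - 12, 10)
  p_enum <- sum(pr[abs(k - ex) >= abs(6 - ex) - 1e-9])
  set.seed(1)
  p_perm <- as.numeric(independence_test(rec, "permutation", n_perm = 40000L))
  expect_lt(abs(p_perm - p_enum), 3 * sqrt(p_enum * (1 - p_enum) / 40000))
  p_fisher <- as.numeric(independence_test(rec, "fisher"))
  expect_lt(abs(p_fisher - p_perm), 0.05)
})

test_that("null p-values are uniform under stochastic loading", {
  # calibration oracle: simulate independent loading, test independence;
  # mid-p with the realized train count removes discreteness conservatism
  set.seed(30)
  cfg <- two_cargo_config(1622, 0.36, 0.08)
  pv <- replicate(500, {
    rec <- cotransport_counts(simulate_traffic(cfg))
    as.numeric(independence_test(rec, "fisher", midp = TRUE,
                                 use_observed_trains = TRUE))
  })
  ks <- suppressWarnings(stats::ks.test(pv, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("simulate() on a fit resamples counts under independence", {
  fit <- cotransport_test(count_record("regen", 578, 130, 104, 1622),
                          method = "none")
  sims <- simulate(fit, nsim = 200, seed = 3)
  n_co <- vapply(sims, `[[`, integer(1), "n_co")
  expected <- fit$p_calc * fit$record$n_trains
  expect_lt(abs(mean(n_co) - expected), 3 * stats::sd(n_co) / sqrt(200))
})

test_that("the packaged count table reproduces every printed cell", {
  tab <- reproduce_table1()
  expect_true(attr(tab, "ok"))
  expect_equal(nrow(tab), 4L)
  # mismatching fixtures are an error in strict mode
  fx <- table1_counts()
  fx$p_calc_printed[1L] <- "0.9"
  expect_error(reproduce_table1(fx), "reproduce")
  expect_error(table1_counts("/nonexistent/file.tsv"), "not found")
})

test_that("power analysis separates the loading models", {
  # at f = 1 the subclass model coincides with stochastic loading and the
  # rejection rate is the test level
  pw <- power_analysis(0.27, 0.12, duration = 905, loading_model = "subclass",
                       f = 1.0, n_sim = 100, seed = 41)
  ci <- stats::qbinom(c(0.005, 0.995), 100, 0.05) / 100
  expect_gte(pw$power, ci[1L])
  expect_lte(pw$power, ci[2L])
  # a strong subclass is detected essentially always
  pw2 <- power_analysis(0.27, 0.12, duration = 905, loading_model = "subclass",
                        f = 0.1, n_sim = 50, seed = 42)
  expect_gt(pw2$power, 0.9)
  expect_error(power_analysis(0.1, 0.1, 100, n_sim = 0), "n_sim")
})
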