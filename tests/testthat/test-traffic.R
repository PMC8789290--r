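test_that("zero observation time yields an empty event table", {
  et <- simulate_traffic(two_cargo_config(0, 0.3, 0.1, seed = 1))
  expect_equal(nrow(et), 0L)
  expect_equal(sum(et$copies_cargoA) + sum(et$copies_cargoB), 0L)
  # a count record needs a positive observation time
  expect_error(count_record("bad", 0, 0, 0, duration = 0), "duration")
})

test_that("identical config and seed give bit-identical event tables", {
  cfg <- two_cargo_config(500, 0.3, 0.1, seed = 42)
  expect_identical(as.data.frame(simulate_traffic(cfg)),
                   as.data.frame(simulate_traffic(cfg)))
})

test_that("cotransport counting conserves totals", {
  et <- simulate_traffic(two_cargo_config(2000, 0.4, 0.2, seed = 7))
  rec <- cotransport_counts(et)
  expect_equal(rec$n_a, sum(et$copies_cargoA > 0))
  expect_equal(rec$n_b, sum(et$copies_cargoB > 0))
  expect_lte(rec$n_co, min(rec$n_a, rec$n_b))
  expect_equal(rec$n_co, sum(et$copies_cargoA > 0 & et$copies_cargoB > 0))
})

test_that("marginals are preserved under both loading models", {
  # checked at T = 1e5 within 4 standard errors
  for (model in c("stochastic", "subclass")) {
    cfg <- two_cargo_config(1e5, 0.27, 0.12, seed = 11,
                            loading_model = model, open_fraction = 0.5)
    et <- simulate_traffic(cfg)
    n <- nrow(et)
    for (p in c(cargoA = 0.27, cargoB = 0.12)) {
      nm <- names(which(c(cargoA = 0.27, cargoB = 0.12) == p))[1L]
      obs <- sum(et[[paste0("copies_", nm)]] > 0) / n
      se <- sqrt(p * (1 - p) / n)
      expect_lt(abs(obs - p), 4 * se)
    }
  }
})

test_that("co-occurrence factorizes under stochastic loading and is enriched 1/f under subclass loading", {
  et <- simulate_traffic(two_cargo_config(1e5, 0.27, 0.12, seed = 3))
  n <- nrow(et)
  a <- et$copies_cargoA > 0; b <- et$copies_cargoB > 0
  p_co <- mean(a & b)
  se <- sqrt(0.27 * 0.12 / n)
  expect_lt(abs(p_co - mean(a) * mean(b)), 4 * se)

  f <- 0.2
  et2 <- simulate_traffic(two_cargo_config(1e5, 0.05, 0.05, seed = 4,
                                           loading_model = "subclass",
                                           open_fraction = f))
  a2 <- et2$copies_cargoA > 0; b2 <- et2$copies_cargoB > 0
  ratio <- mean(a2 & b2) / (mean(a2) * mean(b2))
  expect_lt(abs(ratio - 1 / f), 0.6)
  # cargo never rides a closed train
  expect_true(all(et2$is_open[a2 | b2]))
})

test_that("Monte-Carlo cotransport rates match the closed forms", {
  # stochastic: mean nCo/nTrains over replicates ~ pA * pB
  set.seed(99)
  cfg <- two_cargo_config(1000, 0.27, 0.12)
  rates <- replicate(60, {
    et <- simulate_traffic(cfg)
    rec <- cotransport_counts(et)
    rec$n_co / max(nrow(et), 1)
  })
  expected <- expected_cotransport_probability(0.27, 0.12)
  expect_lt(abs(mean(rates) - expected), 3 * stats::sd(rates) / sqrt(60))

  # subclass with f = 0.2: pA * pB / f
  cfg2 <- two_cargo_config(1000, 0.1, 0.1, loading_model = "subclass",
                           open_fraction = 0.2)
  rates2 <- replicate(60, {
    et <- simulate_traffic(cfg2)
    cotransport_counts(et)$n_co / max(nrow(et), 1)
  })
  expect_equal(expected_cotransport_probability(0.1, 0.1, "subclass", f = 0.2),
               0.05)
  expect_lt(abs(mean(rates2) - 0.05), 3 * stats::sd(rates2) / sqrt(60))
})

test_that("expected cotransport probability handles edge cases", {
  expect_equal(expected_cotransport_probability(0, 0.5), 0)
  expect_equal(expected_cotransport_probability(0.268, 0.117), 0.268 * 0.117)
  # subclass enrichment never exceeds the rarer cargo's marginal
  expect_equal(expected_cotransport_probability(0.3, 0.4, "subclass", f = 0.05),
               0.3)
  expect_error(expected_cotransport_probability(0.1, 0.1, "subclass", f = 0),
               "open fraction")
})

test_that("regular arrival spacing gives exactly duration x rate trains", {
  cfg <- two_cargo_config(100, 0.3, 0.1, seed = 1, arrival = "regular")
  et <- simulate_traffic(cfg)
  expect_equal(nrow(et), 100L)
  expect_true(all(diff(et$departure_time_s) == 1))
})
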