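test_that("a deterministic pool dwell delays the first fluorescent transport", {
  cfg <- sim_config(duration = 250, pool_dwell_mean = 19, pool_dwell_sd = 0,
                    seed = 31)
  et <- simulate_pool_bleach(cfg, bleach_time = 100)
  fl <- et$fluor_cargoA
  post <- et$departure_time_s > 100 & et$departure_time_s <= 119
  expect_true(all(fl[post] == 0L))
  gap <- detect_traffic_gap(et)
  expect_gte(gap, 19)
  expect_false(attr(gap, "censored"))
})

test_that("mean measured gap recovers the pool dwell time", {
  set.seed(77)
  gaps <- replicate(50, {
    cfg <- sim_config(duration = 150, pool_dwell_mean = 19, pool_dwell_sd = 7.7)
    detect_traffic_gap(simulate_pool_bleach(cfg, bleach_time = 40))
  })
  se <- stats::sd(gaps) / sqrt(length(gaps))
  expect_lt(abs(mean(gaps) - 19), 3 * se)
})

test_that("bleaching after the window end is rejected", {
  cfg <- sim_config(duration = 50, seed = 1)
  expect_error(simulate_pool_bleach(cfg, bleach_time = 50), "earlier")
  expect_error(simulate_pool_bleach(cfg, bleach_time = 120), "earlier")
})

test_that("incomplete recovery thins post-gap fluorescent traffic", {
  cfg <- sim_config(duration = 2000, pool_dwell_mean = 19, pool_dwell_sd = 0,
                    seed = 13)
  et <- simulate_pool_bleach(cfg, bleach_time = 100, recovery_fraction = 0.4)
  post <- et$departure_time_s > 119 & et$copies_cargoA > 0
  frac <- sum(et$fluor_cargoA[post]) / sum(et$copies_cargoA[post])
  expect_lt(abs(frac - 0.4), 0.1)
})

test_that("gap detection works on event times directly", {
  et <- manual_event_table(times = c(5, 30), copies = c(1L, 1L),
                           duration = 60)
  gap <- detect_traffic_gap(et, bleach_time = 10)
  expect_equal(as.numeric(gap), 20)
  # censored when nothing follows the bleach
  gap2 <- detect_traffic_gap(et, bleach_time = 40)
  expect_true(attr(gap2, "censored"))
  expect_equal(as.numeric(gap2), 20)
  expect_error(detect_traffic_gap(et, bleach_time = 70), "window")
})
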