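test_that("the run segment lasts length/velocity", {
  cfg <- sim_config(duration = 60, flagellum_length = 10,
                    cargoes = list(cargo_adapter("a")), seed = 1)
  ev <- list(train_id = 1L, departure_time_s = 0, velocity_um_s = 1.71,
             copies_a = 1L)
  tr <- build_trajectory(ev, "a", cfg)
  run <- tr$segments[tr$segments$kind == "run", ]
  expect_equal(run$t1 - run$t0, 10 / 1.71, tolerance = 1e-12)
  expect_equal(c(run$x0, run$x1), c(0, 10))
})

test_that("zero dwell spread gives exactly the mean dwell", {
  cfg <- sim_config(duration = 60, tip_dwell_mean = 2.3, tip_dwell_sd = 0,
                    cargoes = list(cargo_adapter("a")), seed = 2)
  for (i in 1:5) {
    tr <- build_trajectory(list(train_id = i, departure_time_s = 1,
                                velocity_um_s = 1.71, copies_a = 1L),
                           "a", cfg)
    d <- tr$segments[tr$segments$kind == "tip_dwell", ]
    expect_equal(d$t1 - d$t0, 2.3)
  }
})

test_that("release fates follow the configured partition", {
  # adapter-like cargo: retrograde return for ~1/15 of trajectories
  cfg <- sim_config(duration = 1, cargoes = list(cargo_adapter("a")), seed = 5)
  set.seed(5)
  n <- 10000L
  fates <- vapply(seq_len(n), function(i) {
    tr <- build_trajectory(list(train_id = i, departure_time_s = 0,
                                velocity_um_s = 1.71, copies_a = 1L),
                           "a", cfg)
    kinds <- tr$segments$kind
    if ("docked" %in% kinds) "dock"
    else if ("retrograde" %in% kinds) "retrograde" else "diffuse"
  }, character(1))
  n_retro <- sum(fates == "retrograde")
  ci <- stats::qbinom(c(0.0005, 0.9995), n, 1 / 15)
  expect_gte(n_retro, ci[1L])
  expect_lte(n_retro, ci[2L])
  expect_equal(sum(fates == "dock"), 0L)
})

test_that("trajectories are contiguous, bounded, and start at the base", {
  cfg <- sim_config(duration = 30, seed = 8)
  et <- simulate_traffic(cfg)
  trajs <- build_trajectories(et, cfg)
  expect_gt(length(trajs), 0L)
  for (tr in trajs) {
    seg <- tr$segments
    expect_equal(seg$kind[1L], "run")
    expect_equal(seg$x0[1L], 0)
    expect_equal(seg$t0[-1L], seg$t1[-nrow(seg)])    # contiguous in time
    t <- seq(seg$t0[1L], max(seg$t1), length.out = 50L)
    x <- trajectory_position(tr, t)
    expect_true(all(is.na(x) | (x >= -1e-9 & x <= cfg$flagellum_length + 1e-9)))
  }
})

test_that("cargo absent from the manifest is a precondition error", {
  cfg <- sim_config(duration = 10, seed = 1)
  ev <- list(train_id = 1L, departure_time_s = 0, velocity_um_s = 1.7,
             copies_cargoA = 0L)
  expect_error(build_trajectory(ev, "cargoA", cfg), "does not carry")
  expect_error(build_trajectory(ev, "nosuch", cfg), "unknown cargo")
})
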