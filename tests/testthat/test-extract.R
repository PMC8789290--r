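single_run_kymo <- function(noise = FALSE, v = 1.71, seed = 1) {
  cfg <- sim_config(duration = 10, antero_velocity_mean = v,
                    antero_velocity_sd = 0, tip_dwell_mean = 2.3,
                    tip_dwell_sd = 0,
                    cargoes = list(cargo_adapter("a", p_load = 1)))
  et <- manual_event_table(times = 1, copies = 1L, duration = 10,
                           velocity = v)
  tr <- build_trajectory(list(train_id = 1L, departure_time_s = 1,
                              velocity_um_s = v, copies_a = 1L), "a", cfg)
  img <- imaging_config(bleach_rate = c(0, 0))
  render_kymograph(list(tr), img, duration = 10, length = 7.3,
                   seed = seed, noise = noise)
}

test_that("a single noiseless run is recovered with its velocity", {
  set.seed(2)
  kymo <- single_run_kymo(noise = FALSE)
  tracks <- extract_tracks(kymo)
  ev <- which(iftcargo:::track_attr(tracks, "is_anterograde_event") > 0)
  expect_equal(length(ev), 1L)
  expect_lt(abs(attr(tracks$tracks[[ev]], "velocity") - 1.71), 0.05)
})

test_that("a blank kymograph yields zero tracks", {
  img <- imaging_config()
  kymo <- render_kymograph(list(), img, duration = 20, length = 7.3, seed = 4)
  tracks <- extract_tracks(kymo)
  expect_equal(length(tracks$tracks), 0L)
  ms <- measure_transport(tracks)
  expect_equal(ms$frequency_per_min, c(0, 0))
  expect_true(all(is.na(ms$velocity_mean)))
})

test_that("uncalibrated input is rejected", {
  expect_error(extract_tracks(matrix(0, 5, 5)), "calibrated")
})

test_that("frequency is transport count scaled to events per minute", {
  ts <- manual_track_set(n_events = 11, duration = 15)
  ms <- measure_transport(ts)
  expect_equal(ms$frequency_per_min[1L], 11 / 15 * 60)
  expect_equal(ms$frequency_per_min[1L], 44)
})

test_that("tip dwell is recovered on sparse noiseless traffic", {
  set.seed(6)
  cfg <- sim_config(duration = 10, tip_dwell_mean = 2.3, tip_dwell_sd = 0,
                    cargoes = list(cargo_adapter("a", p_load = 1)))
  tr <- build_trajectory(list(train_id = 1L, departure_time_s = 1,
                              velocity_um_s = 1.71, copies_a = 1L), "a", cfg)
  img <- imaging_config(bleach_rate = c(0, 0))
  kymo <- render_kymograph(list(tr), img, 10, 7.3, seed = 3, noise = FALSE)
  tracks <- extract_tracks(kymo)
  dw <- iftcargo:::track_attr(tracks, "tip_dwell")
  expect_true(any(!is.na(dw)))
  expect_lt(abs(dw[which(!is.na(dw))[1L]] - 2.3), 0.4)
})

test_that("simulated tip dwells are recovered from ground truth within 0.2 s", {
  # sample-mean oracle over 500 trajectories
  set.seed(12)
  cfg <- sim_config(duration = 1, tip_dwell_mean = 2.3, tip_dwell_sd = 1.8,
                    cargoes = list(cargo_adapter("a")))
  dwells <- replicate(500, {
    tr <- build_trajectory(list(train_id = 1L, departure_time_s = 0,
                                velocity_um_s = 1.71, copies_a = 1L), "a", cfg)
    d <- tr$segments[tr$segments$kind == "tip_dwell", ]
    d$t1 - d$t0
  })
  # the gamma dwell draw has mean exactly equal to the configured value
  expect_lt(abs(mean(dwells) - 2.3), 0.2)
  expect_true(all(dwells >= 0))
})

test_that("cotransport calling pairs identical trajectories and is symmetric", {
  cfg <- sim_config(duration = 30, seed = 17,
                    cargoes = list(cargo_adapter("a", p_load = 0.3)))
  et <- simulate_traffic(cfg)
  trajs <- build_trajectories(et, cfg)
  # render the same trajectories into both channels
  trajs2 <- lapply(trajs, function(tr) { tr$channel <- 2L; tr })
  img <- imaging_config(bleach_rate = c(0, 0))
  kymo <- render_kymograph(c(trajs, trajs2), img, 30, 7.3, seed = 5,
                           noise = FALSE)
  tracks <- extract_tracks(kymo)
  co <- call_cotransports(tracks)
  expect_gt(co$record$n_a, 0L)
  expect_equal(co$record$n_co, min(co$record$n_a, co$record$n_b))
  # symmetry: swap the channels and recount
  kymo_sw <- kymo
  kymo_sw$channels <- rev(kymo_sw$channels)
  co_sw <- call_cotransports(extract_tracks(kymo_sw))
  expect_equal(co_sw$record$n_co, co$record$n_co)
})

test_that("tracks separated beyond tolerance are never paired", {
  cfg <- sim_config(duration = 20, seed = 19,
                    cargoes = list(cargo_adapter("a", p_load = 1)))
  t1 <- build_trajectory(list(train_id = 1L, departure_time_s = 1,
                              velocity_um_s = 1.71, copies_a = 1L), "a", cfg)
  t2 <- build_trajectory(list(train_id = 2L, departure_time_s = 8,
                              velocity_um_s = 1.71, copies_a = 1L), "a", cfg)
  t2$channel <- 2L
  img <- imaging_config(bleach_rate = c(0, 0))
  kymo <- render_kymograph(list(t1, t2), img, 20, 7.3, noise = FALSE)
  co <- call_cotransports(extract_tracks(kymo))
  expect_equal(co$record$n_co, 0L)
})

test_that("frequency estimate is invariant to photon level above the detection floor", {
  freqs <- vapply(c(1, 2, 4), function(mult) {
    cfg <- sim_config(duration = 60, seed = 23,
                      cargoes = list(cargo_adapter("a", p_load = 0.3)))
    et <- simulate_traffic(cfg)
    trajs <- build_trajectories(et, cfg)
    img <- imaging_config(photons_per_particle = 150 * mult,
                          bleach_rate = c(0, 0))
    kymo <- render_kymograph(trajs, img, 60, 7.3, seed = 29)
    ms <- measure_transport(extract_tracks(kymo), kymo)
    ms$frequency_per_min[1L]
  }, numeric(1))
  expect_lt(max(freqs) - min(freqs), 0.15 * max(freqs))
})
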