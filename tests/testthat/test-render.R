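no_bleach_img <- function(...) imaging_config(bleach_rate = c(0, 0), ...)

run_trajectory <- function(t0 = 0, v = 1.71, L = 7.3, copies = 1L,
                           channel = 1L, dwell = 0) {
  seg <- data.frame(kind = c("run", "tip_dwell"),
                    t0 = c(t0, t0 + L / v), t1 = c(t0 + L / v, t0 + L / v + dwell),
                    x0 = c(0, L), x1 = c(L, L), stringsAsFactors = FALSE)
  structure(list(label = "a", channel = channel, train_id = 1L,
                 copies = as.integer(copies), segments = seg,
                 diff_path = NULL, bleach_time = NA_real_),
            class = "cargo_trajectory")
}

docked_trajectory <- function(x, t0 = 0, t1 = 60, copies = 1L, channel = 1L) {
  seg <- data.frame(kind = "docked", t0 = t0, t1 = t1, x0 = x, x1 = x,
                    stringsAsFactors = FALSE)
  structure(list(label = "a", channel = channel, train_id = 1L,
                 copies = as.integer(copies), segments = seg,
                 diff_path = NULL, bleach_time = NA_real_),
            class = "cargo_trajectory")
}

test_that("an empty trajectory list renders pure background", {
  img <- no_bleach_img()
  kymo <- render_kymograph(list(), img, duration = 20, length = 7.3, seed = 1)
  m <- kymo$channels[[1L]]
  expect_lt(abs(mean(m) - img$background), 3 * sqrt(img$background / length(m)))
  expect_error(render_kymograph(list(), img, duration = 0, length = 7.3),
               "duration")
})

test_that("a noise-free run renders as a straight line at its velocity", {
  img <- no_bleach_img()
  tr <- run_trajectory(v = 1.71)
  kymo <- render_kymograph(list(tr), img, duration = 6, length = 7.3,
                           seed = 1, noise = FALSE)
  m <- kymo$channels[[1L]] - img$background
  # peak column per frame while the particle is in transit
  frames <- 2:40
  peak_col <- apply(m[frames, ], 1L, which.max)
  t_mid <- (frames - 0.5) / img$frame_rate
  fit <- stats::lm(peak_col ~ t_mid)
  v_fit <- stats::coef(fit)[2L] * img$pixel_size
  expect_lt(abs(v_fit - 1.71), 0.05)
})

test_that("photon flux is conserved and doubles with copy number", {
  img <- no_bleach_img()
  tr1 <- docked_trajectory(x = 3.5, copies = 1L)
  tr2 <- docked_trajectory(x = 3.5, copies = 2L)
  k1 <- render_kymograph(list(tr1), img, 60, 7.3, noise = FALSE)
  k2 <- render_kymograph(list(tr2), img, 60, 7.3, noise = FALSE)
  sig1 <- rowSums(k1$channels[[1L]] - img$background)
  sig2 <- rowSums(k2$channels[[1L]] - img$background)
  expect_equal(mean(sig1), img$photons_per_particle, tolerance = 1e-3)
  expect_equal(mean(sig2), 2 * img$photons_per_particle, tolerance = 1e-3)
  # and in expectation under noise, over >= 1e3 frames within 3 SE
  kn <- render_kymograph(list(docked_trajectory(x = 3.5, t1 = 120)),
                         img, 120, 7.3, seed = 3)
  sig <- rowSums(kn$channels[[1L]]) - ncol(kn$channels[[1L]]) * img$background
  se <- stats::sd(sig) / sqrt(length(sig))
  expect_lt(abs(mean(sig) - img$photons_per_particle), 3 * se)
})

test_that("noise-free rendering is linear in the trajectory set", {
  img <- no_bleach_img()
  ta <- run_trajectory(t0 = 1)
  tb <- docked_trajectory(x = 2.0)
  k_union <- render_kymograph(list(ta, tb), img, 20, 7.3, noise = FALSE)
  k_a <- render_kymograph(list(ta), img, 20, 7.3, noise = FALSE)
  k_b <- render_kymograph(list(tb), img, 20, 7.3, noise = FALSE)
  expect_equal(k_union$channels[[1L]],
               k_a$channels[[1L]] + k_b$channels[[1L]] - img$background,
               tolerance = 1e-12)
})

test_that("bleaching the whole flagellum at time zero blanks the kymograph", {
  img <- no_bleach_img()
  trajs <- list(run_trajectory(t0 = 1), docked_trajectory(x = 2.0))
  dark <- bleach_region(trajs, region = c(0, 7.3), time = 0 + 1e-9)
  # the run has not yet entered at t=0, so only pre-loaded signal bleaches;
  # bleach later, while both are inside
  dark2 <- bleach_region(trajs, region = c(0, 7.3), time = 2)
  kymo <- render_kymograph(dark2, img, 20, 7.3, noise = FALSE)
  after <- kymo$channels[[1L]][30:200, ]
  expect_equal(max(after), img$background, tolerance = 1e-9)
})

test_that("tip bleaching spares proximal anterograde signal", {
  img <- no_bleach_img()
  trajs <- list(docked_trajectory(x = 7.0),   # docked near the tip
                run_trajectory(t0 = 6))       # enters after the bleach pulse
  dark <- bleach_region(trajs, region = c(6, 7.3), time = 3)
  kymo <- render_kymograph(dark, img, 10, 7.3, noise = FALSE)
  m <- kymo$channels[[1L]] - img$background
  tip_col <- round(7.0 / img$pixel_size + img$pad_px + 0.5)
  expect_equal(max(m[40:90, tip_col]), 0, tolerance = 1e-6)
  expect_gt(max(m[70:100, ]), img$photons_per_particle * 0.2)
})

test_that("identical seeds render identical kymographs", {
  trajs <- list(run_trajectory())
  img <- imaging_config()
  k1 <- render_kymograph(trajs, img, 10, 7.3, seed = 9)
  k2 <- render_kymograph(trajs, img, 10, 7.3, seed = 9)
  expect_identical(k1$channels, k2$channels)
})
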