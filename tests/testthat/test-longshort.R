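test_that("the control preset reproduces the published group means", {
  pairs <- simulate_long_short(10000, seed = 51)
  se_s <- stats::sd(pairs$freq_short) / 100
  se_l <- stats::sd(pairs$freq_long) / 100
  expect_lt(abs(mean(pairs$freq_short) - 29.1), 3 * se_s)
  expect_lt(abs(mean(pairs$freq_long) - 8.9), 3 * se_l)
  expect_true(all(pairs$length_short <= pairs$length_long))
  expect_true(all(pairs$freq_short >= 0 & pairs$freq_long >= 0))
})

test_that("the cycloheximide preset reproduces its group means and cohort size", {
  pairs <- simulate_long_short(treatment = "chx", seed = 52)
  expect_equal(nrow(pairs), 14L)
  big <- simulate_long_short(10000, treatment = "chx", seed = 53)
  expect_lt(abs(mean(big$freq_short) - 33), 3 * stats::sd(big$freq_short) / 100)
  expect_lt(abs(mean(big$freq_long) - 10.2), 3 * stats::sd(big$freq_long) / 100)
  # default control cohort matches the published analysis
  expect_equal(nrow(simulate_long_short(seed = 1)), 19L)
})

test_that("equal lengths give equal expected frequencies", {
  fm <- function(own, delta) 20 + 2 * abs(delta) * sign(delta < 0)
  preset <- longshort_preset("control")
  # at zero length difference both flagella sit at the anchor frequency
  expect_equal(preset$anchor + preset$slope_short * 0,
               preset$anchor - preset$slope_long * 0)
})

test_that("trend fitting recovers exact lines and rejects degenerate input", {
  d <- data.frame(delta_length = 1:6,
                  freq_short = 2 * (1:6) + 1,
                  freq_long = -0.5 * (1:6) + 10)
  tf <- suppressWarnings(fit_trend(d))
  expect_equal(tf$slope[tf$group == "short"], 2)
  expect_equal(tf$intercept[tf$group == "short"], 1)
  expect_equal(tf$slope[tf$group == "long"], -0.5)
  expect_error(fit_trend(d[1, ]), "at least 2")
  d$delta_length <- 3
  expect_error(fit_trend(d), "degenerate")
})

test_that("fitted trends recover the preset's signs", {
  signs <- replicate(100, {
    tf <- fit_trend(simulate_long_short(19))
    c(tf$slope[tf$group == "short"], tf$slope[tf$group == "long"])
  })
  set.seed(55)
  expect_gt(mean(signs[1, ] > 0), 0.95)      # short flagellum rises with delta
  expect_lt(mean(signs[2, ]), 0.5)           # long flagellum flat or declining
})

test_that("trend fits are shift-equivariant in frequency", {
  pairs <- simulate_long_short(50, seed = 56)
  tf0 <- fit_trend(pairs)
  shifted <- pairs
  shifted$freq_short <- shifted$freq_short + 7
  shifted$freq_long <- shifted$freq_long + 7
  tf1 <- fit_trend(shifted)
  expect_equal(tf1$slope, tf0$slope)
  expect_equal(tf1$intercept, tf0$intercept + 7)
})

test_that("short-flagellum mean exceeds long-flagellum mean in nearly all cohorts", {
  set.seed(57)
  wins <- replicate(200, {
    p <- simulate_long_short(19)
    mean(p$freq_short) > mean(p$freq_long)
  })
  expect_gte(mean(wins), 0.95)
})
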