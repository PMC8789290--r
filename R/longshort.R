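#' Presets for the paired long-short flagella experiment
#'
#' A long-short (long-zero) cell regrows an amputated flagellum while the
#' other one shortens, so cargo transport can be compared at two lengths
#' within one cell. The presets reproduce the published group means: under
#' the `"control"` condition the adapter is transported at 29.1 events/min
#' (SD 16) in the shorter and 8.9 events/min (SD 6.8) in the longer
#' flagellum; under cycloheximide (`"chx"`, protein synthesis blocked) the
#' means are 33 (SD 13.2) and 10.2 (SD 8.1) events/min. Mean frequency is
#' modeled as linear in the length difference between the flagella, anchored
#' at both groups' common value when the lengths are equal; 14.4 events/min,
#' the frequency measured in half-length flagella arrested by cycloheximide,
#' is used as that anchor. The slopes are calibrated so the population means
#' under the preset's length-difference distribution (uniform given a long
#' flagellum of 10-13 um) equal the published group means exactly; residual
#' cell-to-cell variation is gamma noise sized so the total group SDs match
#' the published ones.
#'
#' @param treatment `"control"` or `"chx"`.
#' @return A list with the anchor frequency, per-group slopes, residual SDs,
#'   the default cohort size, and the length-difference distribution bounds.
#' @export
longshort_preset <- function(treatment = c("control", "chx")) {
  treatment <- match.arg(treatment)
  anchor <- 14.4                 # events/min at equal lengths
  long_range <- c(10, 13)        # um; length difference ~ U(0, long - 1.5)
  mean_delta <- (mean(long_range) - 1.5) / 2
  # Var of delta: E[Var|long] + Var(E|long) with delta | long ~ U(0, long-1.5)
  a2 <- long_range[1L] - 1.5; b2 <- long_range[2L] - 1.5
  e_x2 <- (a2^2 + a2 * b2 + b2^2) / 3        # E[(long-1.5)^2], long uniform
  var_delta <- e_x2 / 12 + ((b2 - a2)^2 / 12) / 4
  if (treatment == "control") {
    mean_short <- 29.1; sd_short <- 16
    mean_long <- 8.9; sd_long <- 6.8
    n_default <- 19L
  } else {
    mean_short <- 33; sd_short <- 13.2
    mean_long <- 10.2; sd_long <- 8.1
    n_default <- 14L
  }
  slope_short <- (mean_short - anchor) / mean_delta
  slope_long <- (anchor - mean_long) / mean_delta
  resid_var_short <- max(sd_short^2 - slope_short^2 * var_delta, 1)
  resid_var_long <- max(sd_long^2 - slope_long^2 * var_delta, 1)
  list(treatment = treatment, anchor = anchor,
       slope_short = slope_short, slope_long = slope_long,
       resid_sd_short = sqrt(resid_var_short),
       resid_sd_long = sqrt(resid_var_long),
       n_default = n_default, long_range = long_range,
       mean_short = mean_short, mean_long = mean_long)
}

#' Simulate a cohort of long-short cells
#'
#' Each cell draws a long-flagellum length and a length difference, then
#' per-flagellum transport frequencies around the preset's mean model with
#' gamma-distributed cell-to-cell noise (non-negative, mean-exact). A custom
#' `freq_model` replaces the preset's mean model: it is called as
#' `freq_model(own_length, delta)` with `delta` the signed length difference
#' `own - other`, and must return the mean frequency (events/min).
#'
#' @param n_cells Number of cells (default: the preset's published cohort
#'   size, 19 control / 14 cycloheximide).
#' @param treatment `"control"` or `"chx"`.
#' @param freq_model Optional function `(own_length, delta) -> mean freq`.
#' @param noise_sd Residual SD (events/min) used with a custom `freq_model`
#'   (length 1 or 2: short, long).
#' @param seed Optional integer seed.
#' @return An object of class `flagella_pairs`: a data frame with one row
#'   per cell (`cell`, `treatment`, `length_long`, `length_short`,
#'   `delta_length`, `freq_long`, `freq_short`).
#' @examples
#' pairs <- simulate_long_short(19, seed = 1)
#' fit_trend(pairs)
#' @export
simulate_long_short <- function(n_cells = NULL,
                                treatment = c("control", "chx"),
                                freq_model = NULL, noise_sd = c(5, 5),
                                seed = NULL) {
  treatment <- match.arg(treatment)
  preset <- longshort_preset(treatment)
  if (is.null(n_cells)) n_cells <- preset$n_default
  if (n_cells < 1L) stop("n_cells must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  long <- stats::runif(n_cells, preset$long_range[1L], preset$long_range[2L])
  delta <- stats::runif(n_cells, 0, long - 1.5)
  short <- long - delta
  if (is.null(freq_model)) {
    mu_short <- preset$anchor + preset$slope_short * delta
    mu_long <- pmax(preset$anchor - preset$slope_long * delta, 0.5)
    sd_short <- preset$resid_sd_short
    sd_long <- preset$resid_sd_long
  } else {
    mu_short <- vapply(seq_len(n_cells),
                       function(i) freq_model(short[i], -delta[i]), numeric(1))
    mu_long <- vapply(seq_len(n_cells),
                      function(i) freq_model(long[i], delta[i]), numeric(1))
    if (length(noise_sd) == 1L) noise_sd <- rep(noise_sd, 2L)
    sd_short <- noise_sd[1L]; sd_long <- noise_sd[2L]
  }
  rgamma_mean <- function(n, mu, sd) {
    shape <- (mu / sd)^2
    stats::rgamma(n, shape = shape, rate = shape / mu)
  }
  freq_short <- rgamma_mean(n_cells, mu_short, sd_short)
  freq_long <- rgamma_mean(n_cells, mu_long, sd_long)
  structure(data.frame(cell = seq_len(n_cells), treatment = treatment,
                       length_long = long, length_short = short,
                       delta_length = delta,
                       freq_long = freq_long, freq_short = freq_short),
            class = c("flagella_pairs", "data.frame"))
}

#' Fit frequency-versus-length-difference trendlines
#'
#' Ordinary least squares of transport frequency on the length difference
#' between the two flagella, separately for the short and the long
#' flagellum of each cell (the two trendlines of the paired-flagella plot).
#'
#' @param pairs A `flagella_pairs` data frame (columns `delta_length`,
#'   `freq_short`, `freq_long`).
#' @return An object of class `trend_fit`: a data frame with one row per
#'   group (`slope`, `intercept`, `resid_sd`, `n`), with the two `lm` fits
#'   attached as attribute `models`.
#' @export
fit_trend <- function(pairs) {
  stopifnot(is.data.frame(pairs))
  if (nrow(pairs) < 2L) stop("at least 2 flagella pairs are required")
  if (stats::var(pairs$delta_length) == 0)
    stop("length differences are degenerate (all equal); no trend can be fit")
  fit_s <- stats::lm(freq_short ~ delta_length, data = pairs)
  fit_l <- stats::lm(freq_long ~ delta_length, data = pairs)
  row <- function(group, fit) {
    data.frame(group = group,
               slope = unname(stats::coef(fit)[2L]),
               intercept = unname(stats::coef(fit)[1L]),
               resid_sd = summary(fit)$sigma,
               n = nrow(pairs))
  }
  structure(rbind(row("short", fit_s), row("long", fit_l)),
            class = c("trend_fit", "data.frame"),
            models = list(short = fit_s, long = fit_l))
}

#' @export
print.trend_fit <- function(x, ...) {
  cat("frequency vs length-difference trend (events/min per um)\n")
  for (r in seq_len(nrow(x)))
    cat(sprintf("  %-5s slope %7.3f, intercept %7.3f (residual SD %.3g, n = %d)\n",
                x$group[r], x$slope[r], x$intercept[r], x$resid_sd[r], x$n[r]))
  invisible(x)
}

#' Plot a long-short cohort with trendlines
#'
#' Squares: short flagella; triangles: long flagella; solid line: long-group
#' trend; dashed line: short-group trend.
#'
#' @param x A `flagella_pairs` data frame.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.flagella_pairs <- function(x, ...) {
  graphics::plot(x$delta_length, x$freq_short, pch = 15,
                 xlab = "length difference (um)",
                 ylab = "transport frequency (events/min)",
                 ylim = range(0, x$freq_short, x$freq_long), ...)
  graphics::points(x$delta_length, x$freq_long, pch = 17, col = "grey40")
  tf <- fit_trend(x)
  graphics::abline(tf$intercept[tf$group == "short"],
                   tf$slope[tf$group == "short"], lty = 2)
  graphics::abline(tf$intercept[tf$group == "long"],
                   tf$slope[tf$group == "long"], lty = 1, col = "grey40")
  graphics::legend("topleft", pch = c(15, 17), lty = c(2, 1),
                   col = c("black", "grey40"),
                   legend = c("short flagellum", "long flagellum"), bty = "n")
  invisible(x)
}
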