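#' Simulate, render, extract and re-measure: the full imaging round trip
#'
#' For each simulated flagellum the pipeline (1) draws train traffic and
#' cargo loading, (2) builds cargo trajectories, (3) renders the two-channel
#' kymograph with noise and photobleaching, (4) extracts tracks, and (5)
#' compares recovered transport statistics against the ground truth. Results
#' are pooled over `n_cells` flagella.
#'
#' @param config A [sim_config()].
#' @param img An [imaging_config()].
#' @param n_cells Number of flagella to simulate.
#' @param seed Integer seed for the whole experiment.
#' @param params [extract_params()] for the extraction step.
#' @param channel Channel on which recovery statistics are reported.
#' @return An object of class `roundtrip`: truth and recovered frequencies
#'   (events/min), velocity and tip-dwell estimates, track recall/precision,
#'   cotransport counts (when both channels carry cargo), and per-cell
#'   details.
#' @export
roundtrip <- function(config, img = imaging_config(), n_cells = 1L,
                      seed = NULL, params = extract_params(), channel = 1L) {
  if (!is.null(seed)) set.seed(seed)
  cells <- vector("list", n_cells)
  for (i in seq_len(n_cells)) {
    cfg <- config
    cfg$seed <- NULL                      # one RNG stream for the experiment
    et <- simulate_traffic(cfg)
    trajs <- build_trajectories(et, cfg)
    kymo <- render_kymograph(trajs, img, duration = cfg$duration,
                             length = cfg$flagellum_length)
    tracks <- extract_tracks(kymo, params)
    ms <- measure_transport(tracks, kymo)
    mt <- match_tracks(tracks, trajs, kymo, channel = channel)
    cn <- cargo_names(et)
    truth_n <- vapply(cn, function(nm) sum(et[[paste0("copies_", nm)]] > 0),
                      numeric(1))
    co <- if (length(cn) >= 2L && all(c(1L, 2L) %in% track_channel(tracks)))
      call_cotransports(tracks)$record else NULL
    cells[[i]] <- list(truth_n = truth_n, measured = ms, match = mt,
                       cotransports = co,
                       truth_visible = mt$n_truth)
  }
  dur_total <- n_cells * config$duration
  row_ch <- function(ms) ms[ms$channel == channel, , drop = FALSE]
  n_rec <- sum(vapply(cells, function(cl) row_ch(cl$measured)$n_anterograde,
                      numeric(1)))
  n_truth <- sum(vapply(cells, function(cl) cl$truth_n[channel], numeric(1)))
  vel_means <- vapply(cells, function(cl) row_ch(cl$measured)$velocity_mean,
                      numeric(1))
  vel_ns <- vapply(cells, function(cl) row_ch(cl$measured)$n_anterograde,
                   numeric(1))
  dw_occ <- vapply(cells, function(cl) row_ch(cl$measured)$tip_dwell_occupancy,
                   numeric(1))
  dw_trk <- vapply(cells, function(cl) row_ch(cl$measured)$tip_dwell_mean,
                   numeric(1))
  dw_n <- vapply(cells, function(cl) row_ch(cl$measured)$n_dwells, numeric(1))
  rec_all <- vapply(cells, function(cl) cl$match$n_matched, numeric(1))
  truth_vis <- vapply(cells, function(cl) cl$match$n_truth, numeric(1))
  trk_all <- vapply(cells, function(cl) cl$match$n_tracks, numeric(1))
  trk_matched <- vapply(cells, function(cl) cl$match$n_tracks_matched,
                        numeric(1))
  wmean <- function(x, w) {
    ok <- is.finite(x) & is.finite(w) & w > 0
    if (!any(ok)) return(NA_real_)
    sum(x[ok] * w[ok]) / sum(w[ok])
  }
  structure(
    list(n_cells = n_cells, duration_total = dur_total, channel = channel,
         truth_frequency = n_truth / dur_total * 60,
         recovered_frequency = n_rec / dur_total * 60,
         velocity_mean = wmean(vel_means, vel_ns),
         tip_dwell_mean = wmean(dw_occ, vel_ns),
         tip_dwell_track_mean = wmean(dw_trk, dw_n),
         recall = sum(rec_all) / max(sum(truth_vis), 1),
         precision = sum(trk_matched) / max(sum(trk_all), 1),
         cells = cells, config = config, imaging = img),
    class = "roundtrip"
  )
}

#' @export
print.roundtrip <- function(x, ...) {
  cat(sprintf("imaging round trip: %d flagell%s, %.4g s total (channel %d)\n",
              x$n_cells, if (x$n_cells == 1L) "um" else "a",
              x$duration_total, x$channel))
  cat(sprintf("  frequency: truth %.3g, recovered %.3g events/min\n",
              x$truth_frequency, x$recovered_frequency))
  cat(sprintf("  anterograde velocity: %.3g um/s (configured %.3g)\n",
              x$velocity_mean, x$config$antero_velocity_mean))
  cat(sprintf("  tip dwell (occupancy): %.3g s (configured %.3g); per-track %.3g s\n",
              x$tip_dwell_mean, x$config$tip_dwell_mean,
              x$tip_dwell_track_mean))
  cat(sprintf("  track recall %.3g, precision %.3g\n", x$recall, x$precision))
  invisible(x)
}
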