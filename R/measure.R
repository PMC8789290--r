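# Estimated fluorophore multiplicity of each track's anterograde run, from
# its integrated (background-subtracted) flux in units of one fluorophore.
# Near-coincident trains that merge into a single bright track, and trains
# carrying two cargo copies, both show up as multiplicity 2.
track_multiplicity <- function(tracks, img) {
  fl <- track_attr(tracks, "run_flux")
  if (is.null(img) || img$photons_per_particle <= 0)
    return(ifelse(is.na(fl), 1, 1))
  # promote to a double only on strong flux evidence (>= 1.6 fluorophore
  # equivalents); higher apparent multiplicities are tip-pool or crossing
  # contamination rather than credible triple coincidences
  m <- ifelse(fl / img$photons_per_particle >= 1.6, 2, 1)
  m[!is.finite(m)] <- 1
  m
}

#' Summarize transport events measured on a kymograph
#'
#' Computes, per channel, the number of anterograde and retrograde transport
#' events, the transport frequency (events/min/flagellum), the anterograde
#' velocity mean and SD, and the tip-dwell mean and SD. Per-track tip dwells
#' follow the operational definition: the time between an anterograde run's
#' arrival within `d_tip_px` of the distal end and the first subsequent
#' displacement by more than `move_px`; dwells cut short by the track ending
#' (bleaching, recording end, or loss under crowding) are censored and
#' excluded from the mean. At dense, regenerating-flagellum traffic several
#' particles dwell at the tip simultaneously and per-track dwells become
#' unreliable; see [estimate_tip_dwell()] for the occupancy-based estimator.
#'
#' @param tracks A [extract_tracks()] `track_set`.
#' @param kymo Optional kymograph the tracks came from; if supplied (with
#'   its imaging configuration) the occupancy-based tip-dwell estimate is
#'   included as `tip_dwell_occupancy`.
#' @return An object of class `transport_summary` (data frame, one row per
#'   channel).
#' @export
measure_transport <- function(tracks, kymo = NULL) {
  stopifnot(inherits(tracks, "track_set"))
  ch <- track_channel(tracks)
  ev <- track_attr(tracks, "is_anterograde_event") > 0
  re <- track_attr(tracks, "is_retrograde_event") > 0
  vel <- track_attr(tracks, "velocity")
  dw <- track_attr(tracks, "tip_dwell")
  cen <- track_attr(tracks, "dwell_censored") > 0
  dur <- tracks$duration
  mult <- track_multiplicity(tracks, if (is.null(kymo)) NULL else kymo$imaging)
  out <- lapply(1:2, function(c) {
    sel <- which(ch == c & ev)
    dsel <- which(ch == c & ev & !is.na(dw) & !is.na(cen) & !cen)
    occ <- if (!is.null(kymo) && !is.null(kymo$imaging))
      estimate_tip_dwell(kymo, tracks, channel = c) else NA_real_
    data.frame(channel = c,
               n_anterograde = sum(mult[sel]),
               n_antero_tracks = length(sel),
               n_retrograde = sum(ch == c & re, na.rm = TRUE),
               frequency_per_min = sum(mult[sel]) / dur * 60,
               velocity_mean = if (length(sel)) mean(vel[sel], na.rm = TRUE) else NA_real_,
               velocity_sd = if (length(sel) > 1L) stats::sd(vel[sel]) else NA_real_,
               tip_dwell_mean = if (length(dsel)) mean(dw[dsel]) else NA_real_,
               tip_dwell_sd = if (length(dsel) > 1L) stats::sd(dw[dsel]) else NA_real_,
               n_dwells = length(dsel),
               tip_dwell_occupancy = occ,
               duration_s = dur,
               flagellum_length_um = tracks$length_um)
  })
  structure(do.call(rbind, out), class = c("transport_summary", "data.frame"))
}

#' Occupancy-based tip-dwell estimator
#'
#' Estimates the mean tip dwell from the time-integral of tip occupancy
#' divided by the number of arriving fluorophores (Little's law), which
#' remains unbiased when several particles dwell at the tip simultaneously
#' and per-track dwell reading breaks down. Dwelling cargo is stationary at
#' the tip for many consecutive frames, whereas cargo diffusing past the tip
#' moves by several pixels per frame, so the tip intensity is first passed
#' through a temporal running median that keeps the static (dwelling) signal
#' and suppresses transients; the matched-filter amplitude of the
#' tip-centered point-spread profile, in units of one fluorophore and
#' rounded to the nearest integer, then counts the dwelling fluorophores per
#' frame. Arrivals are weighted by their estimated copy number (integrated
#' run flux in fluorophore units), and single-step photobleaching, which
#' truncates observed dwells, is inverted to first order using the known
#' bleach rate.
#'
#' @param kymo A rendered kymograph (its `imaging` configuration supplies
#'   the photon yield and bleach rate).
#' @param tracks The `track_set` extracted from `kymo` (arrival count).
#' @param channel Channel to analyze.
#' @param median_frames Width (frames, odd) of the temporal running median.
#' @return Estimated mean tip dwell (s), or `NA` if no arrivals were seen.
#' @export
estimate_tip_dwell <- function(kymo, tracks, channel = 1L, median_frames = 5L) {
  stopifnot(inherits(kymo, "kymograph"), inherits(tracks, "track_set"))
  img <- kymo$imaging
  if (is.null(img)) stop("kymograph has no imaging configuration")
  params <- tracks$params
  mat <- kymo$channels[[channel]]
  fps <- kymo$frame_rate
  sigma <- img$psf_sigma_px
  c_tip <- kymo_col(kymo, kymo$length_um)
  w <- ceiling(3 * sigma) + 1L
  cols <- max(1L, floor(c_tip - w)):min(ncol(mat), ceiling(c_tip + w))
  # temporal running median per column: static dwell signal survives,
  # moving particles (arriving trains, departing diffusers) are suppressed
  sub <- apply(mat[, cols, drop = FALSE], 2L, stats::runmed,
               k = median_frames, endrule = "median")
  p <- stats::pnorm((cols + 0.5 - c_tip) / sigma) -
    stats::pnorm((cols - 0.5 - c_tip) / sigma)
  # balanced matched filter (zero mean): rejects the flat and linearly
  # sloped background pedestal laid down by diffusing cargo, while one
  # fluorophore dwelling at the tip responds with exactly
  # photons_per_particle by construction
  w <- p - mean(p)
  resp <- sub %*% w / sum(p * w)
  occ <- round(resp / img$photons_per_particle)
  occ[occ < 0] <- 0

  ch <- track_channel(tracks)
  ev <- track_attr(tracks, "is_anterograde_event") > 0
  dw <- track_attr(tracks, "tip_dwell")
  # every anterograde run ends at the tip, but tracks are often lost inside
  # the crowded tip cluster before the dwell registers; count an arrival
  # whenever the run's fitted line reaches the tip within the recording
  nframes <- nrow(mat)
  cand <- which(ch == channel & ev)
  if (length(cand) == 0L) return(NA_real_)
  arrives <- vapply(cand, function(i) {
    tr <- tracks$tracks[[i]]
    if (!is.na(dw[i])) return(TRUE)
    rr <- attr(tr, "run_range")
    sel <- tr$frame >= rr[1L] & tr$frame <= rr[2L]
    f <- tr$frame[sel]; x <- tr$x[sel]
    if (length(f) < 2L || stats::var(f) == 0) return(FALSE)
    v <- stats::cov(f, x) / stats::var(f)
    if (v <= 0) return(FALSE)
    f_tip <- f[length(f)] + (c_tip - x[length(x)]) / v
    f_tip <= nframes - 1L
  }, logical(1))
  arr_idx <- cand[arrives]
  if (length(arr_idx) == 0L) return(NA_real_)
  # fluorophores per arrival from the integrated run flux
  mult <- track_multiplicity(tracks, img)[arr_idx]
  n_fluor <- sum(mult)
  # a running median keeps the endpoints of an interval that is on for at
  # least (median_frames + 1)/2 frames, so no edge correction is needed
  total <- sum(occ) / fps
  m <- total / n_fluor
  if (!is.finite(m) || m <= 0) return(NA_real_)
  # first-order bleach correction: the observed dwell is min(dwell, bleach
  # time), so E[obs] = E[dwell] - beta * E[dwell^2] / 2 + O(beta^2)
  beta <- img$bleach_rate[channel]
  if (beta > 0) {
    cen <- track_attr(tracks, "dwell_censored") > 0
    dsel <- which(ch == channel & ev & !is.na(dw) & !is.na(cen) & !cen)
    s <- if (length(dsel) > 3L) stats::sd(dw[dsel]) else 0.8 * m
    m <- m * (1 + beta * (m^2 + s^2) / (2 * m))
  }
  m
}

#' Pair anterograde tracks across channels into cotransports
#'
#' Two anterograde events (one per channel) are called a cotransport when
#' their anterograde runs overlap in time by at least `min_overlap` of the
#' shorter run and their mean position difference over the shared frames is
#' at most `tolerance_px`. Candidate pairs are matched greedily one-to-one
#' by ascending mean distance, so the call is symmetric in channel order.
#'
#' @param tracks A `track_set` containing both channels (or a list of two
#'   `track_set`s).
#' @param tolerance_px Mean position tolerance (pixels), default 2.
#' @param min_overlap Minimum temporal overlap fraction of the shorter run.
#' @param label Label for the resulting [count_record()].
#' @return A list with `pairs` (data frame of matched track ids and mean
#'   distances) and `record` (a `count_record` with nA, nB, nCo, duration).
#' @export
call_cotransports <- function(tracks, tolerance_px = 2, min_overlap = 0.5,
                              label = "extracted") {
  stopifnot(inherits(tracks, "track_set"))
  ch <- track_channel(tracks)
  ev <- track_attr(tracks, "is_anterograde_event") > 0
  ia <- which(ch == 1L & ev)
  ib <- which(ch == 2L & ev)
  runs <- lapply(tracks$tracks, function(tr) {
    rr <- attr(tr, "run_range")
    sel <- tr$frame >= rr[1L] & tr$frame <= rr[2L] & tr$label == "anterograde"
    tr[sel, c("frame", "x")]
  })
  cand <- list()
  for (i in ia) for (j in ib) {
    a <- runs[[i]]; b <- runs[[j]]
    shared <- intersect(a$frame, b$frame)
    if (length(shared) == 0L) next
    if (length(shared) / min(nrow(a), nrow(b)) < min_overlap) next
    d <- mean(abs(a$x[match(shared, a$frame)] - b$x[match(shared, b$frame)]))
    if (d <= tolerance_px)
      cand[[length(cand) + 1L]] <- c(i = i, j = j, d = d)
  }
  pairs <- data.frame(track_a = integer(0), track_b = integer(0),
                      mean_dist_px = numeric(0))
  if (length(cand) > 0L) {
    cm <- do.call(rbind, cand)
    cm <- cm[order(cm[, "d"]), , drop = FALSE]
    used_a <- integer(0); used_b <- integer(0)
    for (r in seq_len(nrow(cm))) {
      if (cm[r, "i"] %in% used_a || cm[r, "j"] %in% used_b) next
      used_a <- c(used_a, cm[r, "i"]); used_b <- c(used_b, cm[r, "j"])
      pairs <- rbind(pairs, data.frame(track_a = cm[r, "i"],
                                       track_b = cm[r, "j"],
                                       mean_dist_px = cm[r, "d"]))
    }
  }
  rec <- count_record(label = label, n_a = length(ia), n_b = length(ib),
                      n_co = nrow(pairs), duration = tracks$duration)
  list(pairs = pairs, record = rec)
}

#' Measure the traffic gap after a basal-pool bleach
#'
#' The gap is the time from the bleach to the first subsequent fluorescent
#' anterograde departure. On an event table from [simulate_pool_bleach()]
#' departures of fluorescent cargo are read directly; on a `track_set` the
#' first anterograde event starting after the bleach is used. If no
#' post-bleach event exists, the gap is censored at the window end (returned
#' with attribute `censored = TRUE`).
#'
#' @param x An `event_table` or `track_set`.
#' @param bleach_time Bleach time (s); defaults to the table's recorded
#'   bleach time if present.
#' @param cargo Cargo name (event tables only; defaults to the bleached one).
#' @return Gap (s), with attribute `censored`.
#' @export
detect_traffic_gap <- function(x, bleach_time = NULL, cargo = NULL) {
  UseMethod("detect_traffic_gap")
}

#' @export
detect_traffic_gap.event_table <- function(x, bleach_time = NULL, cargo = NULL) {
  if (is.null(bleach_time)) bleach_time <- attr(x, "bleach_time")
  if (is.null(bleach_time)) stop("bleach_time is required")
  cfg <- attr(x, "config")
  if (bleach_time < 0 || bleach_time >= cfg$duration)
    stop("bleach_time must lie within the observation window")
  if (is.null(cargo)) cargo <- attr(x, "bleached_cargo")
  if (is.null(cargo)) cargo <- cargo_names(x)[1L]
  fcol <- paste0("fluor_", cargo)
  counts <- if (fcol %in% names(x)) x[[fcol]] else x[[paste0("copies_", cargo)]]
  t_next <- x$departure_time_s[counts > 0 & x$departure_time_s > bleach_time]
  if (length(t_next) == 0L)
    return(structure(cfg$duration - bleach_time, censored = TRUE))
  structure(min(t_next) - bleach_time, censored = FALSE)
}

#' @export
detect_traffic_gap.track_set <- function(x, bleach_time = NULL, cargo = NULL) {
  if (is.null(bleach_time)) stop("bleach_time is required")
  if (bleach_time < 0 || bleach_time >= x$duration)
    stop("bleach_time must lie within the observation window")
  ev <- track_attr(x, "is_anterograde_event") > 0
  starts <- vapply(x$tracks, function(tr) {
    rr <- attr(tr, "run_range")
    rr[1L] / x$frame_rate
  }, numeric(1))
  t_next <- starts[ev & !is.na(starts) & starts > bleach_time]
  if (length(t_next) == 0L)
    return(structure(x$duration - bleach_time, censored = TRUE))
  structure(min(t_next) - bleach_time, censored = FALSE)
}

#' Match extracted tracks to ground-truth trajectories
#'
#' Ground-truth anterograde events are the rendered trajectories whose
#' anterograde run is fluorescently visible for at least `min_frames`
#' frames. An extracted anterograde track matches a truth event when the
#' two overlap in time and their mean position difference over the shared
#' frames is at most `tol_px` pixels; matching is greedy one-to-one by
#' ascending distance.
#'
#' @param tracks A `track_set`.
#' @param trajectories The trajectory list that was rendered.
#' @param kymo The rendered kymograph (calibration and recorded per-copy
#'   bleach times).
#' @param channel Channel to evaluate.
#' @param tol_px Mean position tolerance (pixels).
#' @return A list with `recall`, `precision`, `n_truth`, `n_tracks`,
#'   `n_matched` and the per-event match table.
#' @export
match_tracks <- function(tracks, trajectories, kymo, channel = 1L, tol_px = 2) {
  stopifnot(inherits(tracks, "track_set"), inherits(kymo, "kymograph"))
  fps <- kymo$frame_rate
  params <- tracks$params
  # visible truth runs
  truth <- list()
  for (i in seq_along(trajectories)) {
    traj <- trajectories[[i]]
    if (traj$channel != channel) next
    run <- traj$segments[traj$segments$kind == "run", ]
    b <- kymo$bleach_times[[i]]
    t_off <- if (is.null(b)) Inf else max(b)
    t1 <- min(run$t1, kymo$duration, t_off)
    if (t1 <= run$t0) next
    f0 <- ceiling(run$t0 * fps + 0.5); f1 <- floor(t1 * fps + 0.5)
    f0 <- max(1L, f0); f1 <- min(nrow(kymo$channels[[1L]]), f1)
    if (f1 - f0 + 1L < params$min_frames) next
    # visibility criterion aligned with the extractor's event definition:
    # a run must cover min_run_um of visible displacement, relaxed to
    # boundary_run_um when it is truncated by the recording window
    vis_disp <- (t1 - run$t0) / (run$t1 - run$t0) * abs(run$x1 - run$x0)
    trunc_by_window <- run$t1 > kymo$duration
    disp_needed <- if (trunc_by_window) params$boundary_run_um else
      params$min_run_um
    if (vis_disp < disp_needed) next
    frames <- f0:f1
    t_mid <- (frames - 0.5) / fps
    x <- trajectory_position(traj, t_mid)
    truth[[length(truth) + 1L]] <- list(index = i, frames = frames,
                                        cols = kymo_col(kymo, x))
  }
  ev <- which(track_channel(tracks) == channel &
                track_attr(tracks, "is_anterograde_event") > 0)
  cand <- list()
  for (ti in seq_along(truth)) {
    tv <- truth[[ti]]
    for (k in seq_along(ev)) {
      tr <- tracks$tracks[[ev[k]]]
      rr <- attr(tr, "run_range")
      sel <- tr$frame >= rr[1L] & tr$frame <= rr[2L]
      shared <- intersect(tr$frame[sel], tv$frames)
      if (length(shared) < max(3L, 0.3 * min(sum(sel), length(tv$frames)))) next
      d <- mean(abs(tr$x[match(shared, tr$frame)] -
                      tv$cols[match(shared, tv$frames)]))
      if (d <= tol_px)
        cand[[length(cand) + 1L]] <- c(ti = ti, k = k, d = d)
    }
  }
  matched <- data.frame(truth = integer(0), track = integer(0),
                        mean_dist_px = numeric(0))
  # a bright track may account for several coincident truth events, up to
  # its apparent fluorophore content (uncapped here: for attribution the
  # question is how many events the track could explain, not how many are
  # credible transports)
  capacity <- rep(1L, length(ev))
  if (!is.null(kymo$imaging) && kymo$imaging$photons_per_particle > 0) {
    fl <- track_attr(tracks, "run_flux")[ev]
    capacity <- pmax(1L, pmin(3L, ceiling(fl / kymo$imaging$photons_per_particle - 0.2)))
    capacity[!is.finite(capacity)] <- 1L
  }
  if (length(cand) > 0L) {
    cm <- do.call(rbind, cand)
    cm <- cm[order(cm[, "d"]), , drop = FALSE]
    used_t <- integer(0)
    for (r in seq_len(nrow(cm))) {
      k <- cm[r, "k"]
      if (cm[r, "ti"] %in% used_t || capacity[k] <= 0L) next
      used_t <- c(used_t, cm[r, "ti"])
      capacity[k] <- capacity[k] - 1L
      matched <- rbind(matched,
                       data.frame(truth = cm[r, "ti"], track = ev[k],
                                  mean_dist_px = cm[r, "d"]))
    }
  }
  list(recall = if (length(truth)) nrow(matched) / length(truth) else NA_real_,
       precision = if (length(ev))
         length(unique(matched$track)) / length(ev) else NA_real_,
       n_truth = length(truth), n_tracks = length(ev),
       n_matched = nrow(matched),
       n_tracks_matched = length(unique(matched$track)), matches = matched)
}

#' @export
print.transport_summary <- function(x, ...) {
  cat("transport summary\n")
  for (r in seq_len(nrow(x))) {
    cat(sprintf(
      "  channel %d: %d anterograde (%.3g/min), %d retrograde; v = %.3g +/- %.3g um/s",
      x$channel[r], x$n_anterograde[r], x$frequency_per_min[r],
      x$n_retrograde[r], x$velocity_mean[r], x$velocity_sd[r]))
    if (!is.na(x$tip_dwell_mean[r]))
      cat(sprintf("; tip dwell %.3g s (n = %d)", x$tip_dwell_mean[r],
                  x$n_dwells[r]))
    if (!is.na(x$tip_dwell_occupancy[r]))
      cat(sprintf("; occupancy dwell %.3g s", x$tip_dwell_occupancy[r]))
    cat("\n")
  }
  invisible(x)
}
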